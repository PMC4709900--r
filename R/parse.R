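# Stage 1: parse raw multiplexed paired-end reads by barcode and cut-site,
# truncate in-line adapter read-through, cull uncalled-base reads,
# quality-trim, and demultiplex into per-genotype files.

#' Describe the restriction-enzyme cut-site remnants of a two-enzyme library
#'
#' Defaults follow the common PstI/MspI protocol: R1 reads are expected to
#' carry `TGCAG` (PstI remnant) immediately after the barcode and R2 reads
#' to start with `CCG` (MspI remnant).  The R1 3' in-line signature marking
#' adapter read-through on short fragments is the reverse-complement of the
#' common-cutter remnant followed by the first 12 bases of the Illumina
#' common adapter.
#'
#' @param rare_remnant Cut-site remnant expected after the barcode on R1.
#' @param common_remnant Cut-site remnant expected at the R2 5' end.
#' @param adapter Illumina common adapter sequence (its first 12 bases form
#'   the in-line signature).
#' @return An object of class `enzyme_pair`.
#' @export
enzyme_pair <- function(rare_remnant = "TGCAG", common_remnant = "CCG",
                        adapter = "AGATCGGAAGAGC") {
  stopifnot(grepl("^[ACGT]+$", rare_remnant), grepl("^[ACGT]+$", common_remnant),
            grepl("^[ACGT]+$", adapter))
  structure(list(
    rare_remnant = rare_remnant,
    common_remnant = common_remnant,
    adapter = adapter,
    common_remnant_rc_plus_adapter = paste0(revcomp_chr(common_remnant),
                                            substr(adapter, 1, 12))
  ), class = "enzyme_pair")
}

#' Assign barcodes to R1 read prefixes
#'
#' Candidate barcodes are compared against the same-length R1 prefix,
#' longest barcodes first; the unique barcode within `max_mismatch`
#' mismatches whose following bases equal the rare-cutter remnant exactly
#' wins.  A distance tie among equal-length candidates is ambiguous and the
#' read is left unassigned.
#'
#' @param r1_seq Character vector of R1 sequences.
#' @param barcode_table Data.frame with `barcode`, `genotype_id`.
#' @param enzymes An [enzyme_pair()].
#' @param max_mismatch Maximum Hamming distance to a barcode (default 1).
#' @return Integer vector of row indices into `barcode_table` (0 = no match).
#' @export
match_barcode <- function(r1_seq, barcode_table, enzymes = enzyme_pair(),
                          max_mismatch = 1L) {
  validate_barcode_table(barcode_table)
  cpp_match_barcodes(r1_seq, barcode_table$barcode, enzymes$rare_remnant,
                     as.integer(max_mismatch))
}

#' Parse raw read pairs by barcode, cut-site and in-line adapter
#'
#' For each pair: the barcode (and by default the rare-cutter remnant) is
#' trimmed from the R1 5' end and the barcode is recorded in both mate
#' headers; the common-cutter remnant is trimmed from the R2 5' end; both
#' mates are truncated where the in-line adapter signature of a
#' shorter-than-read fragment occurs (for R2 the signature is the
#' reverse-complement of barcode plus rare remnant, the sequence that
#' follows the insert on that strand); and pairs in which either mate is a
#' strict majority of N bases are discarded.
#'
#' @param r1,r2 Read tables (data.frames with `id`, `seq`, `qual`) holding
#'   synchronized mates.
#' @param barcode_table Data.frame with `barcode`, `genotype_id`.
#' @param enzymes An [enzyme_pair()].
#' @param max_mismatch Barcode mismatch allowance (default 1).
#' @param remove_remnant Drop the rare-cutter remnant along with the barcode
#'   so positions are comparable across genotypes (default), or retain it.
#' @param enforce_r2_remnant Require the common-cutter remnant at the R2 5'
#'   end (off by default).
#' @param remove_r2_remnant Trim the common-cutter remnant off R2 when
#'   present.
#' @param sig_max_mm Mismatches tolerated in the full in-line adapter
#'   signature (default 1; sequencing errors inside the signature would
#'   otherwise leave adapter tails on the reads).
#' @param r2_remnant_max_mm Mismatches tolerated when recognising the R2
#'   5' remnant for trimming/enforcement (default 1).
#' @return A list with `pairs` (data.frame: `id`, `genotype`, `barcode`,
#'   `seq1`, `qual1`, `seq2`, `qual2`) and `stats` (named integer vector:
#'   `total_pairs`, `barcode_matched`, `cutsite_failed`, `n_culled`,
#'   `retained`).
#' @export
parse_read_pairs <- function(r1, r2, barcode_table, enzymes = enzyme_pair(),
                             max_mismatch = 1L, remove_remnant = TRUE,
                             enforce_r2_remnant = FALSE,
                             remove_r2_remnant = remove_remnant,
                             sig_max_mm = 1L, r2_remnant_max_mm = 1L) {
  validate_barcode_table(barcode_table)
  stopifnot(nrow(r1) == nrow(r2))
  n <- nrow(r1)
  stats <- c(total_pairs = n, barcode_matched = 0L, cutsite_failed = 0L,
             n_culled = 0L, retained = 0L)
  empty <- data.frame(id = character(), genotype = character(),
                      barcode = character(), seq1 = character(),
                      qual1 = character(), seq2 = character(),
                      qual2 = character(), stringsAsFactors = FALSE)
  if (n == 0) return(list(pairs = empty, stats = stats))

  idx <- cpp_match_barcodes(r1$seq, barcode_table$barcode,
                            enzymes$rare_remnant, as.integer(max_mismatch))
  matched <- idx > 0
  stats["barcode_matched"] <- sum(matched)
  if (!any(matched)) return(list(pairs = empty, stats = stats))
  r1 <- r1[matched, , drop = FALSE]
  r2 <- r2[matched, , drop = FALSE]
  idx <- idx[matched]
  bc <- barcode_table$barcode[idx]
  gid <- barcode_table$genotype_id[idx]

  cut1 <- nchar(bc) + if (remove_remnant) nchar(enzymes$rare_remnant) else 0L
  s1 <- substr(r1$seq, cut1 + 1L, nchar(r1$seq))
  q1 <- substr(r1$qual, cut1 + 1L, nchar(r1$qual))

  cr <- enzymes$common_remnant
  has_rem2 <- cpp_prefix_mismatches(r2$seq, cr) <= r2_remnant_max_mm
  keep <- rep(TRUE, length(s1))
  if (enforce_r2_remnant) {
    keep <- has_rem2
    stats["cutsite_failed"] <- sum(!has_rem2)
  }
  s2 <- r2$seq
  q2 <- r2$qual
  if (remove_r2_remnant) {
    cl <- ifelse(has_rem2, nchar(cr), 0L)
    s2 <- substr(s2, cl + 1L, nchar(s2))
    q2 <- substr(q2, cl + 1L, nchar(q2))
  }

  # 3' in-line adapter signatures: leftmost full occurrence wins; a read
  # whose 3' end stops inside the signature (fragment end close to the read
  # end) is trimmed at the longest suffix equal to a signature prefix
  trimmed1 <- trim_signature(s1, q1, enzymes$common_remnant_rc_plus_adapter,
                             sig_max_mm)
  s1 <- trimmed1$seq
  q1 <- trimmed1$qual

  sig2 <- revcomp_chr(paste0(bc, enzymes$rare_remnant))
  for (sg in unique(sig2)) {
    w <- which(sig2 == sg)
    tr <- trim_signature(s2[w], q2[w], sg, sig_max_mm)
    s2[w] <- tr$seq
    q2[w] <- tr$qual
  }

  # strict-majority-N cull on either mate
  n1 <- nchar(s1) - nchar(gsub("N", "", s1, fixed = TRUE))
  n2 <- nchar(s2) - nchar(gsub("N", "", s2, fixed = TRUE))
  cull <- (2L * n1 > nchar(s1)) | (2L * n2 > nchar(s2))
  stats["n_culled"] <- sum(keep & cull)
  keep <- keep & !cull
  stats["retained"] <- sum(keep)

  pairs <- data.frame(
    id = paste(sub("\\s.*$", "", r1$id[keep]), bc[keep]),
    genotype = gid[keep], barcode = bc[keep],
    seq1 = s1[keep], qual1 = q1[keep], seq2 = s2[keep], qual2 = q2[keep],
    stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  list(pairs = pairs, stats = stats)
}

# Truncate reads at an in-line 3' signature: leftmost full occurrence
# (within sig_max_mm mismatches) first, otherwise the longest read suffix
# equal to a signature prefix (partial adapter at the read end; exact below
# 10 bases, one mismatch tolerated at 10+).
trim_signature <- function(seq, qual, sig, sig_max_mm = 1L) {
  if (!length(seq)) return(list(seq = seq, qual = qual))
  cut <- cpp_trim_signature(seq, sig, as.integer(sig_max_mm), 10L)
  hit <- cut >= 0L
  seq[hit] <- substr(seq[hit], 1L, cut[hit])
  qual[hit] <- substr(qual[hit], 1L, cut[hit])
  list(seq = seq, qual = qual)
}

#' Quality-trim reads the Trimmomatic way
#'
#' Leading and trailing bases below `lead_q`/`trail_q` are removed, then the
#' read is scanned 5' to 3' in windows of `window` bases and cut at the
#' start of the first window whose mean Phred score falls below `min_q`.
#' Reads ending up shorter than `min_len` are discarded.  Defaults mirror
#' `LEADING:30 SLIDINGWINDOW:4:30 TRAILING:30 MINLEN:32`.
#'
#' @param seq,qual Character vectors of sequences and Phred+33 qualities.
#' @param window Sliding-window width.
#' @param min_q Minimum mean window Phred score.
#' @param lead_q,trail_q Minimum Phred for leading/trailing bases.
#' @param min_len Minimum surviving read length.
#' @return A data.frame with `seq`, `qual`, `kept`; dropped reads have `NA`
#'   sequence.
#' @export
quality_trim <- function(seq, qual, window = 4L, min_q = 30, lead_q = 30,
                         trail_q = 30, min_len = 32L) {
  stopifnot(length(seq) == length(qual))
  if (!length(seq)) {
    return(data.frame(seq = character(), qual = character(), kept = logical(),
                      stringsAsFactors = FALSE))
  }
  se <- cpp_quality_trim(qual, as.integer(window), min_q,
                         as.integer(lead_q), as.integer(trail_q))
  len <- se[, 2] - se[, 1] + 1L
  kept <- se[, 1] > 0L & len >= min_len
  out <- data.frame(seq = rep(NA_character_, length(seq)),
                    qual = rep(NA_character_, length(seq)),
                    kept = kept, stringsAsFactors = FALSE)
  out$seq[kept] <- substr(seq[kept], se[kept, 1], se[kept, 2])
  out$qual[kept] <- substr(qual[kept], se[kept, 1], se[kept, 2])
  out
}

#' Quality-trim parsed pairs, keeping mates synchronized
#'
#' Both mates are trimmed with [quality_trim()]; pairs in which both mates
#' survive stay pairs, single survivors become singletons (orphaned mates).
#'
#' @param parsed The `pairs` data.frame from [parse_read_pairs()].
#' @inheritParams quality_trim
#' @return A list with `pairs` (both mates kept), `singletons` (data.frame
#'   `id`, `genotype`, `barcode`, `mate`, `seq`, `qual`) and `stats`.
#' @export
trim_read_pairs <- function(parsed, window = 4L, min_q = 30, lead_q = 30,
                            trail_q = 30, min_len = 32L) {
  t1 <- quality_trim(parsed$seq1, parsed$qual1, window, min_q, lead_q, trail_q, min_len)
  t2 <- quality_trim(parsed$seq2, parsed$qual2, window, min_q, lead_q, trail_q, min_len)
  both <- t1$kept & t2$kept
  only1 <- t1$kept & !t2$kept
  only2 <- t2$kept & !t1$kept
  pairs <- parsed[both, , drop = FALSE]
  pairs$seq1 <- t1$seq[both]; pairs$qual1 <- t1$qual[both]
  pairs$seq2 <- t2$seq[both]; pairs$qual2 <- t2$qual[both]
  rownames(pairs) <- NULL
  singles <- rbind(
    data.frame(id = parsed$id[only1], genotype = parsed$genotype[only1],
               barcode = parsed$barcode[only1], mate = rep(1L, sum(only1)),
               seq = t1$seq[only1], qual = t1$qual[only1], stringsAsFactors = FALSE),
    data.frame(id = parsed$id[only2], genotype = parsed$genotype[only2],
               barcode = parsed$barcode[only2], mate = rep(2L, sum(only2)),
               seq = t2$seq[only2], qual = t2$qual[only2], stringsAsFactors = FALSE))
  rownames(singles) <- NULL
  list(pairs = pairs, singletons = singles,
       stats = c(input_pairs = nrow(parsed), retained_pairs = nrow(pairs),
                 singletons = nrow(singles),
                 dropped_pairs = nrow(parsed) - nrow(pairs) - nrow(singles)))
}

#' Split parsed pairs by genotype
#'
#' @param pairs A parsed/trimmed pairs data.frame carrying a `genotype`
#'   column (from [parse_read_pairs()]).
#' @return Named list (one entry per genotype) of pairs data.frames.
#' @export
demultiplex_pairs <- function(pairs) {
  if (is.null(pairs$genotype) || any(is.na(pairs$genotype))) {
    stop("reads lack barcode/genotype annotation; run parse_read_pairs() first",
         call. = FALSE)
  }
  split(pairs, factor(pairs$genotype, levels = unique(pairs$genotype)))
}

#' Write demultiplexed per-genotype FASTQ files
#'
#' One (R1, R2) FASTQ pair per genotype plus a single file of orphaned
#' mates.  Mate order within each genotype is preserved and synchronized.
#'
#' @param pairs Trimmed pairs data.frame.
#' @param singletons Singletons data.frame from [trim_read_pairs()] (may be
#'   empty).
#' @param dir Output directory (created if needed).
#' @param compress Write `.fastq.gz`.
#' @return Manifest data.frame (`genotype`, `n_pairs`, `r1`, `r2`).
#' @export
write_demultiplexed <- function(pairs, singletons = NULL, dir, compress = TRUE) {
  by_g <- demultiplex_pairs(pairs)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (compress) ".fastq.gz" else ".fastq"
  manifest <- data.frame(genotype = names(by_g),
                         n_pairs = vapply(by_g, nrow, integer(1)),
                         r1 = file.path(dir, paste0(names(by_g), ".R1", ext)),
                         r2 = file.path(dir, paste0(names(by_g), ".R2", ext)),
                         stringsAsFactors = FALSE)
  rownames(manifest) <- NULL
  for (i in seq_len(nrow(manifest))) {
    g <- by_g[[i]]
    write_fastq(data.frame(id = g$id, seq = g$seq1, qual = g$qual1),
                manifest$r1[i], compress = compress)
    write_fastq(data.frame(id = g$id, seq = g$seq2, qual = g$qual2),
                manifest$r2[i], compress = compress)
  }
  if (!is.null(singletons)) {
    sp <- file.path(dir, paste0("singletons", ext))
    write_fastq(
      if (nrow(singletons)) {
        data.frame(id = paste0(singletons$id, "/", singletons$mate),
                   seq = singletons$seq, qual = singletons$qual)
      } else empty_read_table(),
      sp, compress = compress)
  }
  manifest
}

#' @rdname parse_read_pairs
#' @param stats Named stats vector as returned in `$stats`.
#' @param path Output path for the tab-separated parsing summary.
#' @export
write_parse_stats <- function(stats, path) {
  utils::write.table(data.frame(metric = names(stats), count = as.integer(stats)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
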