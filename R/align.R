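# Stage 3a: map processed read pairs to the (Mock) reference with
# pair-proper, unique-hit semantics, and summarise base calls as pileups.
# Externally produced samtools-mpileup text is ingested by read_pileup(),
# converging on the same PileupColumn layout.

ref_seqs <- function(reference) {
  if (inherits(reference, "MockReference")) {
    stats::setNames(reference$centroids$seq, reference$centroids$id)
  } else if (is.character(reference) && !is.null(names(reference))) {
    reference
  } else {
    stop("reference must be a MockReference or a named character vector",
         call. = FALSE)
  }
}

# Runs of >= 20 A's mark stitched-read junctions; alignments may not span
# them.
find_a_runs <- function(seq) {
  m <- gregexpr("A{20,}", seq)[[1]]
  if (m[1] < 0) return(NULL)
  cbind(as.integer(m), as.integer(m) + attr(m, "match.length") - 1L)
}

#' Map read pairs to a reference with pair-proper, unique-hit semantics
#'
#' Each mate is aligned by exact-seed lookup and full-length extension over
#' candidate diagonals, on both strands.  A mate with two or more distinct
#' loci at the equal best score is unmapped (no confounding
#' secondary/supplementary evidence is tolerated).  A pair is retained only
#' when both mates map uniquely to the same centroid in opposite
#' orientations with a plausible, non-inverted insert.  Alignments spanning
#' a stitched-read A-junction are rejected.
#'
#' @param pairs Pairs data.frame (`id`, `seq1`, `qual1`, `seq2`, `qual2`,
#'   optionally `genotype`).
#' @param reference A `MockReference` or named character vector of
#'   reference sequences.
#' @param seed_len Exact seed length (default 20).
#' @param seed_step Distance between successive seed positions.
#' @param max_edit_frac Maximum per-read mismatch fraction (default 0.07,
#'   mirroring the 93 % clustering identity so reads that built a centroid
#'   can map back to it).
#' @param max_insert Maximum allowed insert size.
#' @return A data.frame of alignment records (two per retained pair):
#'   `read_id`, `pair_id`, `mate`, `ref_id`, `pos`, `strand`, `cigar`,
#'   `edits`, `mate_pos`, `is_unique`, `seq`, `qual` (reference-oriented),
#'   plus `genotype` when present in the input.  Attribute `stats` records
#'   pair totals.
#' @export
align_read_pairs <- function(pairs, reference, seed_len = 20L, seed_step = 10L,
                             max_edit_frac = 0.07, max_insert = 2000L) {
  refs <- ref_seqs(reference)
  junc <- lapply(unname(refs), find_a_runs)
  n <- nrow(pairs)
  empty <- data.frame(read_id = character(), pair_id = integer(),
                      mate = integer(), ref_id = character(), pos = integer(),
                      strand = character(), cigar = character(),
                      edits = integer(), mate_pos = integer(),
                      is_unique = logical(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE)
  if (!n) {
    attr(empty, "stats") <- c(total_pairs = 0L, mapped_pairs = 0L)
    return(empty)
  }
  m1 <- cpp_map_reads(pairs$seq1, unname(refs), as.integer(seed_len),
                      as.integer(seed_step), max_edit_frac, junc)
  m2 <- cpp_map_reads(pairs$seq2, unname(refs), as.integer(seed_len),
                      as.integer(seed_step), max_edit_frac, junc)
  len1 <- nchar(pairs$seq1)
  len2 <- nchar(pairs$seq2)
  ok <- m1$ref > 0L & m2$ref > 0L & m1$ref == m2$ref & m1$strand != m2$strand
  # orient: f = forward-strand mate, r = reverse-strand mate
  f_pos <- ifelse(m1$strand == "+", m1$pos, m2$pos)
  r_pos <- ifelse(m1$strand == "+", m2$pos, m1$pos)
  r_end <- r_pos + ifelse(m1$strand == "+", len2, len1) - 1L
  proper <- ok & !is.na(f_pos) & f_pos <= r_pos + 5L & r_end >= f_pos &
    (r_end - f_pos + 1L) <= max_insert
  proper[is.na(proper)] <- FALSE
  keep <- which(proper)
  if (!length(keep)) {
    attr(empty, "stats") <- c(total_pairs = n, mapped_pairs = 0L)
    return(empty)
  }
  mk_rec <- function(mate, mm, seq, qual, other) {
    rev <- mm$strand[keep] == "-"
    data.frame(
      read_id = pairs$id[keep],
      pair_id = keep,
      mate = rep(mate, length(keep)),
      ref_id = names(refs)[mm$ref[keep]],
      pos = mm$pos[keep],
      strand = mm$strand[keep],
      cigar = paste0(nchar(seq[keep]), "M"),
      edits = mm$edits[keep],
      mate_pos = other$pos[keep],
      is_unique = rep(TRUE, length(keep)),
      seq = ifelse(rev, revcomp_chr(seq[keep]), seq[keep]),
      qual = ifelse(rev, revstr_chr(qual[keep]), qual[keep]),
      stringsAsFactors = FALSE)
  }
  out <- rbind(mk_rec(1L, m1, pairs$seq1, pairs$qual1, m2),
               mk_rec(2L, m2, pairs$seq2, pairs$qual2, m1))
  out <- out[order(out$pair_id, out$mate), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(pairs$genotype)) out$genotype <- pairs$genotype[out$pair_id]
  attr(out, "stats") <- c(total_pairs = n, mapped_pairs = length(keep))
  out
}

#' Summarise alignments as per-position base-call pileup columns
#'
#' Counts A/C/G/T depths per reference position over aligned bases with
#' Phred quality at least `min_base_q`.  Bases covered by both mates of a
#' pair are counted once (the higher-quality mate wins).  Positions
#' overlapped by an alignment deletion, or flanking an insertion, carry
#' `indel_evidence`.
#'
#' @param alignments Alignment records from [align_read_pairs()] (or
#'   constructed with the same columns; CIGARs may contain M/I/D/S).
#' @param reference A `MockReference` or named character vector.
#' @param min_base_q Minimum base quality to count (default 0).
#' @return A data.frame: `ref_id`, `pos`, `ref_base`, `A`, `C`, `G`, `T`,
#'   `indel_evidence`.
#' @export
make_pileup <- function(alignments, reference, min_base_q = 0L) {
  refs <- ref_seqs(reference)
  empty <- data.frame(ref_id = character(), pos = integer(),
                      ref_base = character(), A = integer(), C = integer(),
                      G = integer(), T = integer(), indel_evidence = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(alignments)) return(empty)
  ri <- match(alignments$ref_id, names(refs))
  if (anyNA(ri)) stop("alignment references a sequence absent from the reference",
                      call. = FALSE)
  o <- order(alignments$pair_id, alignments$mate)
  al <- alignments[o, , drop = FALSE]
  res <- cpp_pileup(ri[o], al$pos, al$seq, al$qual, al$cigar, al$pair_id,
                    nchar(unname(refs)), as.integer(min_base_q))
  data.frame(ref_id = names(refs)[res$ref], pos = res$pos,
             ref_base = substr(unname(refs)[res$ref], res$pos, res$pos),
             A = res$A, C = res$C, G = res$G, T = res$T,
             indel_evidence = res$indel == 1L, stringsAsFactors = FALSE)
}

#' Read a samtools-mpileup text file into pileup columns
#'
#' Parses the classic TAB-separated mpileup dialect (chrom, 1-based pos,
#' reference base, depth, read-bases string, base qualities).  `.`/`,`
#' resolve to the reference base, letter substitutions are case-folded,
#' `^` consumes its mapping-quality character, `$` is ignored, `+n`/`-n`
#' indel runs consume exactly `n` bases and set `indel_evidence`, and `*`
#' (deletion placeholder) sets `indel_evidence`.  A malformed bases string
#' or a depth-field mismatch raises an error naming the line.
#'
#' @param path Path to an mpileup text file.
#' @return A data.frame like [make_pileup()]'s.
#' @export
read_pileup <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4L) {
      stop("mpileup parse error at line ", i, ": fewer than 4 fields", call. = FALSE)
    }
    depth <- suppressWarnings(as.integer(f[4]))
    if (is.na(depth)) {
      stop("mpileup parse error at line ", i, ": bad depth field", call. = FALSE)
    }
    if (depth == 0L && length(f) < 6L) next
    if (length(f) < 6L) {
      stop("mpileup parse error at line ", i, ": missing read-bases string",
           call. = FALSE)
    }
    v <- tryCatch(cpp_parse_mpileup_bases(f[3], f[5]),
                  error = function(e) {
                    stop("mpileup parse error at line ", i, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
    if (v[6] != depth) {
      stop("mpileup parse error at line ", i, ": read-bases string resolves to ",
           v[6], " bases but depth field says ", depth, call. = FALSE)
    }
    out[[i]] <- data.frame(ref_id = f[1], pos = as.integer(f[2]),
                           ref_base = toupper(f[3]), A = v[1], C = v[2],
                           G = v[3], T = v[4], indel_evidence = v[5] == 1L,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(ref_id = character(), pos = integer(),
                      ref_base = character(), A = integer(), C = integer(),
                      G = integer(), T = integer(), indel_evidence = logical(),
                      stringsAsFactors = FALSE)
  }
  keep <- out$A + out$C + out$G + out$T > 0L | out$indel_evidence
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write pileup columns as mpileup-dialect text
#'
#' The inverse of [read_pileup()] for depth information: reference-matching
#' bases are emitted as `.`, substitutions as uppercase letters, all base
#' qualities as `I`; columns with `indel_evidence` carry a `+1A` insertion
#' marker so the flag round-trips.
#'
#' @param pileup A pileup data.frame ([make_pileup()] layout).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(pileup, path) {
  bases <- character(nrow(pileup))
  depth <- pileup$A + pileup$C + pileup$G + pileup$T
  for (b in c("A", "C", "G", "T")) {
    d <- pileup[[b]]
    tok <- ifelse(pileup$ref_base == b, ".", b)
    bases <- paste0(bases, strrep(tok, d))
  }
  bases <- ifelse(pileup$indel_evidence,
                  paste0(substr(bases, 1L, 1L), "+1A",
                         substr(bases, 2L, nchar(bases))),
                  bases)
  writeLines(paste(pileup$ref_id, pileup$pos, pileup$ref_base, depth, bases,
                   strrep("I", depth), sep = "\t"), path)
  invisible(path)
}

#' Export alignment records as SAM text
#'
#' Minimal valid SAM (\code{@HD}/\code{@SQ} header plus the 11 mandatory
#' columns) for interoperability with external pileup generation.
#'
#' @param alignments Alignment records from [align_read_pairs()].
#' @param reference A `MockReference` or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reference, path) {
  refs <- ref_seqs(reference)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", names(refs), "\tLN:", nchar(unname(refs))))
  if (nrow(alignments)) {
    al <- alignments[order(alignments$pair_id, alignments$mate), , drop = FALSE]
    is_rev <- al$strand == "-"
    mate_rev <- rev_by_pair(is_rev, al$pair_id)
    flag <- 1L + 2L + ifelse(is_rev, 16L, 0L) + ifelse(mate_rev, 32L, 0L) +
      ifelse(al$mate == 1L, 64L, 128L)
    body <- paste(sub("\\s.*$", "", al$read_id), flag, al$ref_id, al$pos, 60L,
                  al$cigar, "=", al$mate_pos, 0L, al$seq, al$qual, sep = "\t")
  } else {
    body <- character()
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

# flag helper: the mate's strand within each pair
rev_by_pair <- function(is_rev, pair_id) {
  other <- stats::ave(as.integer(is_rev), pair_id, FUN = function(x) sum(x) - x)
  other > 0L
}
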