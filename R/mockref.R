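# Stage 2: merge or stitch processed mate pairs into full-fragment reads
# and cluster them into a non-redundant centroid set -- the Mock Reference.

#' Merge overlapping mate pairs into full-fragment reads
#'
#' R2 is reverse-complemented into R1 orientation and the longest
#' 3'(R1)-5'(rc R2) overlap of at least `min_overlap` bases with a mismatch
#' fraction within `max_mismatch_frac` justifies merging; at mismatching
#' overlap columns the higher-quality base wins and keeps its quality.
#' Merged reads shorter than `min_len` are discarded.
#'
#' @param pairs Pairs data.frame (`seq1`, `qual1`, `seq2`, `qual2`).
#' @param min_overlap Minimum overlap length in bp (default 10).
#' @param max_mismatch_frac Maximum fraction of mismatching overlap columns.
#' @param min_len Minimum assembled read length (default 32).
#' @return A data.frame with `seq`, `qual`, `status` (one of `"assembled"`,
#'   `"unmerged"`, `"discarded"`), row-parallel to `pairs`.
#' @export
merge_read_pairs <- function(pairs, min_overlap = 10L, max_mismatch_frac = 0.1,
                             min_len = 32L) {
  n <- nrow(pairs)
  if (!n) {
    return(data.frame(seq = character(), qual = character(),
                      status = character(), stringsAsFactors = FALSE))
  }
  res <- cpp_merge_pairs(pairs$seq1, pairs$qual1,
                         revcomp_chr(pairs$seq2), revstr_chr(pairs$qual2),
                         as.integer(min_overlap), max_mismatch_frac)
  status <- ifelse(res$merged,
                   ifelse(nchar(res$seq) >= min_len, "assembled", "discarded"),
                   "unmerged")
  out <- data.frame(seq = as.character(res$seq), qual = as.character(res$qual),
                    status = status, stringsAsFactors = FALSE)
  out$seq[status != "assembled"] <- NA_character_
  out$qual[status != "assembled"] <- NA_character_
  out
}

#' Stitch unmerged mate pairs with a 20-A junction
#'
#' Pairs that could not be overlap-merged (long fragments) are joined as
#' `R1 + AAAA...A (20) + reverse-complement(R2)`; junction qualities are set
#' to Phred 40.  Pairs with either mate shorter than `min_len_each` are
#' discarded.
#'
#' @param pairs Pairs data.frame (`seq1`, `qual1`, `seq2`, `qual2`).
#' @param min_len_each Minimum length of each mate (default 32).
#' @return A data.frame with `seq`, `qual`, `status` (`"stitched"` or
#'   `"discarded"`), row-parallel to `pairs`.
#' @export
stitch_read_pairs <- function(pairs, min_len_each = 32L) {
  n <- nrow(pairs)
  if (!n) {
    return(data.frame(seq = character(), qual = character(),
                      status = character(), stringsAsFactors = FALSE))
  }
  ok <- nchar(pairs$seq1) >= min_len_each & nchar(pairs$seq2) >= min_len_each
  seq <- rep(NA_character_, n)
  qual <- rep(NA_character_, n)
  seq[ok] <- paste0(pairs$seq1[ok], strrep("A", 20L), revcomp_chr(pairs$seq2[ok]))
  qual[ok] <- paste0(pairs$qual1[ok], strrep("I", 20L), revstr_chr(pairs$qual2[ok]))
  data.frame(seq = seq, qual = qual,
             status = ifelse(ok, "stitched", "discarded"),
             stringsAsFactors = FALSE)
}

#' Merge where possible, stitch the rest
#'
#' @inheritParams merge_read_pairs
#' @param min_len_each Minimum mate length for stitching.
#' @return A data.frame with `seq`, `qual`, `origin` (`"assembled"` or
#'   `"stitched"`); discarded pairs are dropped.  Attribute `counts` records
#'   the per-outcome tally.
#' @export
merge_or_stitch <- function(pairs, min_overlap = 10L, max_mismatch_frac = 0.1,
                            min_len = 32L, min_len_each = 32L) {
  m <- merge_read_pairs(pairs, min_overlap, max_mismatch_frac, min_len)
  un <- m$status == "unmerged"
  s <- stitch_read_pairs(pairs[un, , drop = FALSE], min_len_each)
  out <- rbind(
    data.frame(seq = m$seq[m$status == "assembled"],
               qual = m$qual[m$status == "assembled"],
               origin = rep("assembled", sum(m$status == "assembled")),
               stringsAsFactors = FALSE),
    data.frame(seq = s$seq[s$status == "stitched"],
               qual = s$qual[s$status == "stitched"],
               origin = rep("stitched", sum(s$status == "stitched")),
               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  attr(out, "counts") <- c(pairs = nrow(pairs),
                           assembled = sum(m$status == "assembled"),
                           stitched = sum(s$status == "stitched"),
                           discarded = sum(m$status == "discarded") +
                             sum(s$status == "discarded"))
  out
}

#' Pairwise nucleotide identity of two sequences
#'
#' Identity is matches / alignment columns of an ends-free (semi-global)
#' optimal alignment: internal gap columns count as mismatches, terminal
#' (free) gap columns are excluded.  Symmetric in its arguments.
#'
#' @param a,b DNA strings.
#' @param details Also return match/column counts.
#' @return The identity fraction, or a named vector when `details = TRUE`.
#' @export
pairwise_identity <- function(a, b, details = FALSE) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  v <- cpp_identity(a, b)
  if (details) v else unname(v["identity"])
}

#' Greedy first-fit sequence clustering
#'
#' Reads are processed in length-descending order (ties broken
#' lexicographically); each read joins the first existing centroid whose
#' [pairwise_identity()] reaches `threshold`, otherwise it founds a new
#' centroid whose sequence is the read itself (no consensus polishing).
#'
#' @param seqs Character vector of DNA sequences.
#' @param threshold Identity threshold in (0, 1]; default 0.93.
#' @param band Half-width of the alignment band used during clustering.
#' @return A list with `centroids` (data.frame `id`, `seq`, `length`,
#'   `member_count`) and `assignment` (centroid id per input read, in input
#'   order).
#' @export
greedy_cluster <- function(seqs, threshold = 0.93, band = 16L) {
  stopifnot(threshold > 0, threshold <= 1)
  if (!length(seqs)) {
    return(list(centroids = data.frame(id = character(), seq = character(),
                                       length = integer(), member_count = integer(),
                                       stringsAsFactors = FALSE),
                assignment = character()))
  }
  o <- order(-nchar(seqs), seqs, method = "radix")
  sorted <- seqs[o]
  uniq <- unique(sorted)          # first-occurrence order == processing order
  au <- cpp_greedy_cluster(uniq, threshold, as.integer(band), 8L)
  ncent <- max(au)
  founder <- match(seq_len(ncent), au)
  assignment_all <- au[match(seqs, uniq)]
  ids <- sprintf("MR_%0*d", max(4L, nchar(ncent)), seq_len(ncent))
  centroids <- data.frame(id = ids, seq = uniq[founder],
                          length = nchar(uniq[founder]),
                          member_count = tabulate(assignment_all, nbins = ncent),
                          stringsAsFactors = FALSE)
  list(centroids = centroids, assignment = ids[assignment_all])
}

#' Rank genotypes by parsed-read abundance
#'
#' @param read_counts Named vector of parsed-read (pair) counts per
#'   genotype.
#' @param n Number of most read-abundant genotypes to select.
#' @return Character vector of selected genotype ids.
#' @export
select_mockref_genotypes <- function(read_counts, n = 1L) {
  stopifnot(length(read_counts) >= 1, n >= 1)
  o <- order(-read_counts, names(read_counts), method = "radix")
  names(read_counts)[o][seq_len(min(n, length(read_counts)))]
}

#' Build the Mock Reference
#'
#' Clusters each selected genotype's merged/stitched reads into
#' genotype-specific centroids, then (when more than one genotype is
#' selected) clusters the pooled centroids into a master centroid set.  The
#' result carries both the per-centroid sequences and the single
#' concatenated "genome" with centroid-boundary offsets (1-based, closed
#' intervals, matching pileup coordinates).
#'
#' @param reads_by_genotype Named list: genotype id -> character vector of
#'   merged/stitched read sequences (or a data.frame with a `seq` column).
#' @param selected Genotype ids to use (default: all).  See
#'   [select_mockref_genotypes()] for abundance-based selection.
#' @param threshold Identity threshold for clustering (default 0.93).
#' @param n_spacer Number of N bases inserted between centroids in the
#'   concatenated genome (default 0; the mapper instead rejects
#'   junction-spanning alignments via the offsets).
#' @return An object of class `MockReference`: list with `centroids`
#'   (data.frame `id`, `seq`, `length`, `member_count`, `source_genotypes`),
#'   `genome_seq`, `offsets` (data.frame `centroid_id`, `start`, `end`),
#'   `threshold`, `selected`.
#' @export
build_mock_reference <- function(reads_by_genotype, selected = NULL,
                                 threshold = 0.93, n_spacer = 0L) {
  if (is.null(selected)) selected <- names(reads_by_genotype)
  if (!length(selected)) stop("no genotypes selected for the Mock Reference",
                              call. = FALSE)
  missing <- setdiff(selected, names(reads_by_genotype))
  if (length(missing)) {
    stop("selected genotypes not present: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  get_seqs <- function(x) if (is.data.frame(x)) x$seq else as.character(x)
  within <- lapply(selected, function(g) {
    cl <- greedy_cluster(get_seqs(reads_by_genotype[[g]]), threshold)
    cl$centroids$genotype <- rep(g, nrow(cl$centroids))
    cl$centroids
  })
  pooled <- do.call(rbind, within)
  if (is.null(pooled) || !nrow(pooled)) {
    stop("no reads available to build the Mock Reference", call. = FALSE)
  }
  if (length(selected) > 1L) {
    cl2 <- greedy_cluster(pooled$seq, threshold)
    grp <- factor(match(cl2$assignment, cl2$centroids$id),
                  levels = seq_len(nrow(cl2$centroids)))
    centroids <- cl2$centroids
    centroids$member_count <- as.integer(tapply(pooled$member_count, grp, sum))
    centroids$source_genotypes <- I(unname(tapply(pooled$genotype, grp,
                                                  function(g) sort(unique(g)))))
  } else {
    centroids <- pooled[, c("id", "seq", "length", "member_count")]
    centroids$source_genotypes <- I(as.list(pooled$genotype))
  }
  rownames(centroids) <- NULL
  spacer <- strrep("N", n_spacer)
  genome_seq <- paste(centroids$seq, collapse = spacer)
  start <- cumsum(c(1L, head(centroids$length, -1L) + n_spacer))
  offsets <- data.frame(centroid_id = centroids$id, start = start,
                        end = start + centroids$length - 1L,
                        stringsAsFactors = FALSE)
  structure(list(centroids = centroids, genome_seq = genome_seq,
                 offsets = offsets, threshold = threshold, selected = selected),
            class = "MockReference")
}

#' @export
print.MockReference <- function(x, ...) {
  cat("MockReference:", nrow(x$centroids), "centroids,",
      nchar(x$genome_seq), "bp concatenated genome\n")
  cat("  built from genotype(s):", paste(x$selected, collapse = ", "), "\n")
  cat("  identity threshold:", x$threshold, "\n")
  invisible(x)
}

#' Convert between genome and centroid-local coordinates
#'
#' The concatenated-genome offsets are invertible: a genome coordinate maps
#' to a unique (centroid, local position) and back.
#'
#' @param mockref A `MockReference`.
#' @param genome_pos Integer vector of 1-based genome coordinates.
#' @return For `genome_to_centroid`, a data.frame `centroid_id`,
#'   `local_pos`; for `centroid_to_genome`, an integer vector of genome
#'   coordinates.
#' @export
genome_to_centroid <- function(mockref, genome_pos) {
  off <- mockref$offsets
  i <- findInterval(genome_pos, off$start)
  bad <- i < 1L | genome_pos > off$end[pmax(i, 1L)]
  if (any(bad)) stop("genome position outside any centroid (spacer or out of range)",
                     call. = FALSE)
  data.frame(centroid_id = off$centroid_id[i],
             local_pos = genome_pos - off$start[i] + 1L,
             stringsAsFactors = FALSE)
}

#' @param centroid_id,local_pos Centroid ids and 1-based local positions.
#' @rdname genome_to_centroid
#' @export
centroid_to_genome <- function(mockref, centroid_id, local_pos) {
  i <- match(centroid_id, mockref$offsets$centroid_id)
  if (anyNA(i)) stop("unknown centroid id", call. = FALSE)
  if (any(local_pos < 1L | local_pos > mockref$centroids$length[i])) {
    stop("local position outside centroid", call. = FALSE)
  }
  mockref$offsets$start[i] + local_pos - 1L
}

#' Write / read the two Mock Reference FASTA files
#'
#' `MockRef_Genome.fasta` holds the single concatenated record;
#' `MockRef_Clusters.fasta` holds one record per centroid in identical
#' order.
#'
#' @param mockref A `MockReference`.
#' @param dir Output directory.
#' @return Invisibly, the two file paths.
#' @export
write_mock_reference <- function(mockref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gp <- file.path(dir, "MockRef_Genome.fasta")
  cp <- file.path(dir, "MockRef_Clusters.fasta")
  write_fasta(stats::setNames(mockref$genome_seq, "MockRefGenome"), gp)
  write_fasta(stats::setNames(mockref$centroids$seq, mockref$centroids$id), cp)
  invisible(c(genome = gp, clusters = cp))
}

#' @param clusters_path Path to a `MockRef_Clusters.fasta`-style file.
#' @param n_spacer Spacer width used when the genome was concatenated.
#' @rdname write_mock_reference
#' @export
read_mock_reference <- function(clusters_path, n_spacer = 0L) {
  seqs <- read_fasta(clusters_path)
  centroids <- data.frame(id = names(seqs), seq = unname(seqs),
                          length = nchar(unname(seqs)),
                          member_count = NA_integer_, stringsAsFactors = FALSE)
  centroids$source_genotypes <- I(vector("list", nrow(centroids)))
  spacer <- strrep("N", n_spacer)
  genome_seq <- paste(centroids$seq, collapse = spacer)
  start <- cumsum(c(1L, head(centroids$length, -1L) + n_spacer))
  structure(list(centroids = centroids, genome_seq = genome_seq,
                 offsets = data.frame(centroid_id = centroids$id, start = start,
                                      end = start + centroids$length - 1L,
                                      stringsAsFactors = FALSE),
                 threshold = NA_real_, selected = character()),
            class = "MockReference")
}
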