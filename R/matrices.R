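# Step 6: distill pileups into per-genotype count files (indel positions
# excluded), list candidate SNP positions, and assemble the population
# master matrix of per-genotype A/C/G/T depths.

#' Convert one genotype's pileup to a count table
#'
#' One row per covered position; positions carrying indel evidence are
#' dropped entirely (the workflow is SNP-exclusive).
#'
#' @param pileup A pileup data.frame from [make_pileup()] or
#'   [read_pileup()].
#' @return A data.frame: `ref_id`, `pos`, `ref_base`, `A`, `C`, `G`, `T`.
#' @export
pileup_to_counts <- function(pileup) {
  keep <- !pileup$indel_evidence & (pileup$A + pileup$C + pileup$G + pileup$T > 0L)
  out <- pileup[keep, c("ref_id", "pos", "ref_base", "A", "C", "G", "T"),
                drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Positions polymorphic to the reference
#'
#' Liberal, threshold-free candidate listing: any depth on a base other
#' than the reference base qualifies the position.
#'
#' @param counts A count table from [pileup_to_counts()].
#' @return A data.frame `ref_id`, `pos`.
#' @export
polymorphic_candidates <- function(counts) {
  total <- counts$A + counts$C + counts$G + counts$T
  refd <- integer(nrow(counts))
  for (b in c("A", "C", "G", "T")) {
    w <- counts$ref_base == b
    refd[w] <- counts[[b]][w]
  }
  out <- counts[total - refd > 0L, c("ref_id", "pos"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the population master matrix
#'
#' The position set is the union of per-genotype candidate positions
#' (deduplicated, sorted by reference then position), minus any position
#' carrying indel evidence in any genotype (excluded population-wide).
#' Every cell holds the genotype's full A/C/G/T depth 4-tuple at the
#' position, taken from its count table even where that genotype was not
#' itself polymorphic; absent coverage is zero depth.
#'
#' @param counts_by_genotype Named list: genotype id -> count table.
#' @param candidates_by_genotype Optional named list of candidate tables;
#'   computed with [polymorphic_candidates()] when `NULL`.
#' @param indel_positions Optional data.frame `ref_id`, `pos` of positions
#'   with indel evidence anywhere in the population.
#' @return An object of class `master_matrix`: list with `positions`
#'   (data.frame `ref_id`, `pos`, `ref_base`), `depths` (integer array
#'   positions x genotypes x 4 bases) and `genotype_ids`.
#' @export
build_master_matrix <- function(counts_by_genotype,
                                candidates_by_genotype = NULL,
                                indel_positions = NULL) {
  gids <- names(counts_by_genotype)
  if (is.null(gids)) stop("counts_by_genotype must be a named list", call. = FALSE)
  if (is.null(candidates_by_genotype)) {
    candidates_by_genotype <- lapply(counts_by_genotype, polymorphic_candidates)
  }
  cand <- do.call(rbind, c(unname(candidates_by_genotype),
                           list(data.frame(ref_id = character(), pos = integer(),
                                           stringsAsFactors = FALSE))))
  key <- paste(cand$ref_id, cand$pos)
  cand <- cand[!duplicated(key), , drop = FALSE]
  if (!is.null(indel_positions) && nrow(indel_positions)) {
    drop <- paste(cand$ref_id, cand$pos) %in%
      paste(indel_positions$ref_id, indel_positions$pos)
    cand <- cand[!drop, , drop = FALSE]
  }
  o <- order(cand$ref_id, cand$pos, method = "radix")
  cand <- cand[o, , drop = FALSE]
  npos <- nrow(cand)
  pkey <- paste(cand$ref_id, cand$pos)
  ref_base <- rep(NA_character_, npos)
  depths <- array(0L, dim = c(npos, length(gids), 4L),
                  dimnames = list(NULL, gids, c("A", "C", "G", "T")))
  for (g in seq_along(gids)) {
    ct <- counts_by_genotype[[g]]
    m <- match(paste(ct$ref_id, ct$pos), pkey)
    hit <- !is.na(m)
    if (!any(hit)) next
    mi <- m[hit]
    conflict <- !is.na(ref_base[mi]) & ref_base[mi] != ct$ref_base[hit]
    if (any(conflict)) {
      stop("conflicting reference base at ", pkey[mi[conflict][1]],
           " across genotypes; inconsistent references", call. = FALSE)
    }
    ref_base[mi] <- ct$ref_base[hit]
    for (b in 1:4) depths[cbind(mi, g, b)] <- ct[[c("A", "C", "G", "T")[b]]][hit]
  }
  positions <- data.frame(ref_id = cand$ref_id, pos = cand$pos,
                          ref_base = ref_base, stringsAsFactors = FALSE)
  rownames(positions) <- NULL
  structure(list(positions = positions, depths = depths, genotype_ids = gids),
            class = "master_matrix")
}

#' @export
print.master_matrix <- function(x, ...) {
  cat("master_matrix:", nrow(x$positions), "candidate positions x",
      length(x$genotype_ids), "genotypes\n")
  invisible(x)
}

#' Write / read the master matrix as TSV
#'
#' First three columns are `ref_id`, `pos`, `ref_base`; then one
#' comma-delimited `A,C,G,T` depth-string column per genotype.
#'
#' @param master A `master_matrix`.
#' @param path File path.
#' @return `path` (write) or a `master_matrix` (read).
#' @export
write_master_matrix <- function(master, path) {
  df <- master$positions
  for (g in seq_along(master$genotype_ids)) {
    df[[master$genotype_ids[g]]] <- paste(master$depths[, g, 1],
                                          master$depths[, g, 2],
                                          master$depths[, g, 3],
                                          master$depths[, g, 4], sep = ",")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_master_matrix
#' @export
read_master_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  gids <- names(df)[-(1:3)]
  npos <- nrow(df)
  depths <- array(0L, dim = c(npos, length(gids), 4L),
                  dimnames = list(NULL, gids, c("A", "C", "G", "T")))
  for (g in seq_along(gids)) {
    parts <- strsplit(df[[gids[g]]], ",", fixed = TRUE)
    m <- matrix(as.integer(unlist(parts)), ncol = 4L, byrow = TRUE)
    depths[, g, ] <- m
  }
  structure(list(positions = data.frame(ref_id = df$ref_id,
                                        pos = as.integer(df$pos),
                                        ref_base = df$ref_base,
                                        stringsAsFactors = FALSE),
                 depths = depths, genotype_ids = gids),
            class = "master_matrix")
}
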