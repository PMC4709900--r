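# Step 7: independence filter, altStrength bi-allelic filter, depth-based
# genotype assignment, and population-level culls, ending in the final SNP
# genotyping matrix.

#' Parameters for SNP calling and genotyping
#'
#' Defaults are the recommended values for a tetraploid outcrossing
#' population: secondary-allele independence at depth >= 3 in >= 3
#' genotypes; altStrength 0.90 (strict inequality); heterozygotes need >= 3
#' reads of each allele and a minor/major depth ratio strictly above 0.1;
#' homozygotes need depth >= 11 when the other allele has zero reads and
#' >= 48 when it has exactly one; SNPs with < 75 % of genotypes scored or
#' with population average depth <= 4 or >= 200 are culled.
#'
#' @param indep_min_depth Minimum secondary-allele depth per genotype for
#'   the independence filter.
#' @param indep_min_genotypes Minimum number of genotypes carrying the
#'   secondary allele at that depth.
#' @param alt_strength Bi-allelic strength threshold on
#'   2°/(2°+3°+4°) population depth (strict `>`).
#' @param het_min_each Minimum depth of each allele for a heterozygote.
#' @param het_min_ratio Minor/major allele depth ratio a heterozygote must
#'   exceed (strict `>`).
#' @param homo_min_depth_alt0 Minimum homozygote depth when the other
#'   allele's count is zero.
#' @param homo_min_depth_alt1 Minimum homozygote depth when the other
#'   allele's count is one.
#' @param min_called_frac Minimum fraction of genotypes with assigned
#'   states.
#' @param min_avg_depth Cull SNPs with population average depth `<=` this.
#' @param max_avg_depth Cull SNPs with population average depth `>=` this.
#' @param avg_depth_all_genotypes Average depth over all genotypes
#'   including zero-coverage ones (default), or over covered genotypes
#'   only.
#' @param indep_pooled Alternative pooled reading of the independence
#'   filter: require `indep_min_genotypes` carriers at any depth with the
#'   pooled secondary depth at least `indep_min_depth` (off by default; the
#'   per-genotype reading is the default interpretation).
#' @return A list of class `calling_params`.
#' @export
calling_params <- function(indep_min_depth = 3L, indep_min_genotypes = 3L,
                           alt_strength = 0.90, het_min_each = 3L,
                           het_min_ratio = 0.1, homo_min_depth_alt0 = 11L,
                           homo_min_depth_alt1 = 48L, min_called_frac = 0.75,
                           min_avg_depth = 4, max_avg_depth = 200,
                           avg_depth_all_genotypes = TRUE,
                           indep_pooled = FALSE) {
  p <- list(indep_min_depth = as.integer(indep_min_depth),
            indep_min_genotypes = as.integer(indep_min_genotypes),
            alt_strength = alt_strength, het_min_each = as.integer(het_min_each),
            het_min_ratio = het_min_ratio,
            homo_min_depth_alt0 = as.integer(homo_min_depth_alt0),
            homo_min_depth_alt1 = as.integer(homo_min_depth_alt1),
            min_called_frac = min_called_frac, min_avg_depth = min_avg_depth,
            max_avg_depth = max_avg_depth,
            avg_depth_all_genotypes = isTRUE(avg_depth_all_genotypes),
            indep_pooled = isTRUE(indep_pooled))
  stopifnot(p$indep_min_depth >= 0, p$indep_min_genotypes >= 0,
            p$alt_strength >= 0, p$alt_strength <= 1,
            p$het_min_each >= 0, p$het_min_ratio >= 0, p$het_min_ratio <= 1,
            p$homo_min_depth_alt0 >= 0, p$homo_min_depth_alt1 >= 0,
            p$min_called_frac >= 0, p$min_called_frac <= 1,
            p$min_avg_depth >= 0, p$max_avg_depth >= 0)
  class(p) <- "calling_params"
  p
}

#' Rank alleles by population-summed depth
#'
#' Per master-matrix row, bases are ranked from primary (highest summed
#' depth) to quaternary; depth ties are broken by the fixed base order
#' A < C < G < T for reproducibility.
#'
#' @param master A `master_matrix`.
#' @return A data.frame with the ranked bases (`primary`, `secondary`,
#'   `tertiary`, `quaternary`) and their population depths (`d1`..`d4`).
#' @export
allele_ranking <- function(master) {
  sums <- apply(master$depths, c(1, 3), sum)
  if (is.null(dim(sums))) sums <- matrix(sums, ncol = 4L)
  bases <- c("A", "C", "G", "T")
  npos <- nrow(sums)
  rank_base <- matrix(NA_character_, npos, 4L)
  rank_depth <- matrix(0L, npos, 4L)
  work <- sums
  for (r in 1:4) {
    j <- max.col(work, ties.method = "first")
    rank_base[, r] <- bases[j]
    rank_depth[, r] <- sums[cbind(seq_len(npos), j)]
    work[cbind(seq_len(npos), j)] <- -1L
  }
  data.frame(primary = rank_base[, 1], secondary = rank_base[, 2],
             tertiary = rank_base[, 3], quaternary = rank_base[, 4],
             d1 = rank_depth[, 1], d2 = rank_depth[, 2],
             d3 = rank_depth[, 3], d4 = rank_depth[, 4],
             stringsAsFactors = FALSE)
}

# depth of a given base per (position, genotype)
base_depth_matrix <- function(master, base_per_row) {
  npos <- dim(master$depths)[1]
  ng <- dim(master$depths)[2]
  out <- matrix(0L, npos, ng)
  bases <- c("A", "C", "G", "T")
  for (b in 1:4) {
    w <- base_per_row == bases[b]
    if (any(w)) out[w, ] <- master$depths[w, , b, drop = FALSE]
  }
  out
}

#' Independence filter on the secondary allele
#'
#' A candidate SNP passes when the putative secondary allele is observed,
#' at depth at least `indep_min_depth`, in at least `indep_min_genotypes`
#' distinct genotypes -- independent occurrences that sequencing or PCR
#' error is unlikely to reproduce.
#'
#' @param master A `master_matrix`.
#' @param ranking From [allele_ranking()] (computed when `NULL`).
#' @param params A [calling_params()].
#' @return Logical vector, one element per master-matrix row.
#' @export
independence_filter <- function(master, ranking = NULL, params = calling_params()) {
  if (is.null(ranking)) ranking <- allele_ranking(master)
  sec <- base_depth_matrix(master, ranking$secondary)
  if (params$indep_pooled) {
    rowSums(sec > 0L) >= params$indep_min_genotypes &
      rowSums(sec) >= params$indep_min_depth
  } else {
    rowSums(sec >= params$indep_min_depth) >= params$indep_min_genotypes
  }
}

#' Bi-allelic altStrength filter
#'
#' A candidate SNP is strongly bi-allelic when the secondary allele
#' dominates the non-primary depth pool:
#' `d2 / (d2 + d3 + d4) > alt_strength` (strict).  A zero denominator means
#' the position is monomorphic and fails.
#'
#' @param ranking From [allele_ranking()].
#' @param params A [calling_params()].
#' @return Logical vector per row.
#' @export
alt_strength_filter <- function(ranking, params = calling_params()) {
  denom <- ranking$d2 + ranking$d3 + ranking$d4
  denom > 0L & ranking$d2 / pmax(denom, 1L) > params$alt_strength
}

#' Depth-based genotype assignment
#'
#' Given one genotype's depths of the row's primary and secondary alleles:
#' heterozygote iff both depths reach `het_min_each` and the minor/major
#' ratio strictly exceeds `het_min_ratio`; homozygote (for the allele with
#' reads) iff the other allele has zero reads and depth reaches
#' `homo_min_depth_alt0`, or the other allele has exactly one read and
#' depth reaches `homo_min_depth_alt1`; anything else is missing.
#'
#' @param primary_depth,secondary_depth Non-negative integer vectors.
#' @param params A [calling_params()].
#' @return Character vector of states: `"hom_primary"`, `"het"`,
#'   `"hom_secondary"`, `"missing"`.
#' @export
call_genotype <- function(primary_depth, secondary_depth,
                          params = calling_params()) {
  p <- primary_depth
  s <- secondary_depth
  lo <- pmin(p, s)
  hi <- pmax(p, s)
  het <- p >= params$het_min_each & s >= params$het_min_each &
    lo > params$het_min_ratio * hi
  hom_p <- (s == 0L & p >= params$homo_min_depth_alt0) |
    (s == 1L & p >= params$homo_min_depth_alt1)
  hom_s <- (p == 0L & s >= params$homo_min_depth_alt0) |
    (p == 1L & s >= params$homo_min_depth_alt1)
  out <- rep("missing", length(p))
  out[hom_p] <- "hom_primary"
  out[hom_s] <- "hom_secondary"
  out[het] <- "het"
  out
}

#' Population-level culls on called SNPs
#'
#' Retains SNPs with at least `min_called_frac` of genotypes scored and a
#' population average depth strictly between `min_avg_depth` and
#' `max_avg_depth` (so depth <= 4 and depth >= 200 are culled at the
#' defaults).
#'
#' @param summary A summary data.frame with `pct_genotyped` and
#'   `avg_depth` columns (as built by [call_snps()]).
#' @param params A [calling_params()].
#' @return Logical keep vector.
#' @export
population_filters <- function(summary, params = calling_params()) {
  summary$pct_genotyped >= params$min_called_frac * 100 &
    summary$avg_depth > params$min_avg_depth &
    summary$avg_depth < params$max_avg_depth
}

#' Call SNPs and genotypes from the master matrix
#'
#' Pipeline order: allele ranking, independence filter, altStrength filter,
#' per-genotype depth-based genotype assignment, then population-level
#' culls.  Rows whose secondary allele has zero population depth
#' (monomorphic within the population) are dropped before genotyping.
#' The population average depth is the mean over all genotypes of the
#' total (4-base) depth at the position.
#'
#' @param master A `master_matrix`.
#' @param params A [calling_params()].
#' @return An object of class `snp_calls`: list with `summary` (the ten
#'   population-summary columns: `ref_id`, `pos`, `ref_base`, `avg_depth`,
#'   `primary`, `secondary`, `pct_genotyped`, `n_hom_primary`, `n_het`,
#'   `n_hom_secondary`), `states` / `primary_depth` / `secondary_depth`
#'   (SNP x genotype matrices), `genotype_ids`, `params`.
#' @export
call_snps <- function(master, params = calling_params()) {
  ranking <- allele_ranking(master)
  keep <- ranking$d2 > 0L
  keep <- keep & independence_filter(master, ranking, params)
  keep <- keep & alt_strength_filter(ranking, params)
  idx <- which(keep)
  ng <- length(master$genotype_ids)
  sub <- function(m) m[idx, , drop = FALSE]
  pd <- base_depth_matrix(master, ranking$primary)[idx, , drop = FALSE]
  sd <- base_depth_matrix(master, ranking$secondary)[idx, , drop = FALSE]
  states <- matrix(call_genotype(as.vector(pd), as.vector(sd), params),
                   nrow = length(idx), ncol = ng)
  colnames(states) <- master$genotype_ids
  colnames(pd) <- colnames(sd) <- master$genotype_ids
  npos_all <- dim(master$depths)[1]
  tot <- matrix(0L, npos_all, ng)
  for (b in 1:4) tot <- tot + matrix(master$depths[, , b], npos_all, ng)
  tot <- tot[idx, , drop = FALSE]
  avg_depth <- if (params$avg_depth_all_genotypes) {
    rowMeans(tot)
  } else {
    rowSums(tot) / pmax(rowSums(tot > 0L), 1L)
  }
  called <- states != "missing"
  summary <- data.frame(
    ref_id = master$positions$ref_id[idx],
    pos = master$positions$pos[idx],
    ref_base = master$positions$ref_base[idx],
    avg_depth = round(avg_depth, 2),
    primary = ranking$primary[idx],
    secondary = ranking$secondary[idx],
    pct_genotyped = round(100 * rowSums(called) / ng, 2),
    n_hom_primary = rowSums(states == "hom_primary"),
    n_het = rowSums(states == "het"),
    n_hom_secondary = rowSums(states == "hom_secondary"),
    stringsAsFactors = FALSE)
  pop_keep <- population_filters(summary, params)
  out <- list(summary = summary[pop_keep, , drop = FALSE],
              states = states[pop_keep, , drop = FALSE],
              primary_depth = pd[pop_keep, , drop = FALSE],
              secondary_depth = sd[pop_keep, , drop = FALSE],
              genotype_ids = master$genotype_ids, params = params)
  rownames(out$summary) <- NULL
  class(out) <- "snp_calls"
  out
}

#' @export
print.snp_calls <- function(x, ...) {
  cat("snp_calls:", nrow(x$summary), "SNPs x", length(x$genotype_ids),
      "genotypes\n")
  if (nrow(x$summary)) {
    cat("  mean avg_depth:", round(mean(x$summary$avg_depth), 1),
        "| mean % genotyped:", round(mean(x$summary$pct_genotyped), 1), "\n")
  }
  invisible(x)
}

state_code <- c(hom_primary = "P", het = "H", hom_secondary = "S",
                missing = "-")

#' Write the final SNP genotyping matrix
#'
#' Ten population-summary columns, then one column per genotype with cells
#' `state|primary_depth/secondary_depth`; `-` marks an unassigned state
#' (`P` primary homozygote, `H` heterozygote, `S` secondary homozygote).
#'
#' @param calls An `snp_calls` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_matrix <- function(calls, path) {
  df <- calls$summary
  for (g in seq_along(calls$genotype_ids)) {
    df[[calls$genotype_ids[g]]] <- paste0(state_code[calls$states[, g]], "|",
                                          calls$primary_depth[, g], "/",
                                          calls$secondary_depth[, g])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
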