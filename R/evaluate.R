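# Comparing a pipeline run against a simulation's truth tables: centroids
# are located on the true fragments, called SNPs are projected into
# fragment coordinates, and recovery / genotype-state concordance are
# scored.

# Locate each centroid on the true fragment cores.  Stitched centroids are
# split at their A-junction and each arm located separately.  Returns one
# row per located segment: centroid coords -> (fragment, offset, shift).
locate_centroids <- function(mockref, truth) {
  cents <- mockref$centroids
  segs <- list()
  for (i in seq_len(nrow(cents))) {
    runs <- find_a_runs(cents$seq[i])
    bounds <- rbind(c(1L, nchar(cents$seq[i])))
    if (!is.null(runs)) {
      cutpoints <- sort(c(1L, t(cbind(runs[, 1] - 1L, runs[, 2] + 1L)),
                          nchar(cents$seq[i])))
      starts <- cutpoints[seq(1, length(cutpoints), by = 2)]
      ends <- cutpoints[seq(2, length(cutpoints), by = 2)]
      keep <- ends >= starts
      bounds <- cbind(starts[keep], ends[keep])
    }
    for (k in seq_len(nrow(bounds))) {
      segs[[length(segs) + 1L]] <- data.frame(
        centroid_id = cents$id[i], seg_start = bounds[k, 1],
        seg_end = bounds[k, 2], stringsAsFactors = FALSE)
    }
  }
  segs <- do.call(rbind, segs)
  segseq <- substr(cents$seq[match(segs$centroid_id, cents$id)],
                   segs$seg_start, segs$seg_end)
  hits <- cpp_map_reads(segseq, truth$fragments$seq, 20L, 10L, 0.1,
                        vector("list", nrow(truth$fragments)))
  segs$fragment <- ifelse(hits$ref > 0L & hits$strand == "+", hits$ref, NA_integer_)
  segs$frag_start <- ifelse(!is.na(segs$fragment), hits$pos, NA_integer_)
  # unlocated segments may carry a few foreign bases at their ends
  # (untrimmed signature residue in the founding read): retry trimmed
  miss <- which(is.na(segs$fragment) & nchar(segseq) > 40L)
  if (length(miss)) {
    t <- 6L
    sub <- substr(segseq[miss], t + 1L, nchar(segseq[miss]) - t)
    h2 <- cpp_map_reads(sub, truth$fragments$seq, 20L, 10L, 0.1,
                        vector("list", nrow(truth$fragments)))
    ok <- h2$ref > 0L & !is.na(h2$strand) & h2$strand == "+"
    segs$fragment[miss[ok]] <- h2$ref[ok]
    segs$frag_start[miss[ok]] <- h2$pos[ok]
    segs$seg_start[miss[ok]] <- segs$seg_start[miss[ok]] + t
    segs$seg_end[miss[ok]] <- segs$seg_end[miss[ok]] - t
  }
  segs[!is.na(segs$fragment), , drop = FALSE]
}

#' Score a pipeline run against simulation truth
#'
#' Maps called SNP positions into true-fragment coordinates and computes:
#' which planted SNPs satisfy the design filters under the truth (the
#' secondary allele carried by at least `indep_min_genotypes` genotypes),
#' the fraction of those recovered, the per-cell genotype-state concordance
#' at recovered SNPs, and the number of called SNPs not matching any
#' planted site (false positives).
#'
#' @param run A `gbs_run` from [run_gbs_pipeline()].
#' @param truth The `truth` list from [simulate_gbs()].
#' @param params The [calling_params()] used for the run.
#' @return A list: `n_planted`, `n_expected`, `n_recovered`,
#'   `recovery_pct`, `concordance_pct`, `n_false_positives`, `n_called`.
#' @export
evaluate_against_truth <- function(run, truth, params = calling_params()) {
  calls <- run$calls
  segs <- locate_centroids(run$mockref, truth)
  # project each called SNP into fragment coordinates
  s <- calls$summary
  frag <- rep(NA_integer_, nrow(s))
  offset <- rep(NA_integer_, nrow(s))
  if (nrow(s)) {
    for (i in seq_len(nrow(s))) {
      w <- which(segs$centroid_id == s$ref_id[i] &
                   segs$seg_start <= s$pos[i] & segs$seg_end >= s$pos[i])
      if (length(w) == 1L) {
        frag[i] <- segs$fragment[w]
        offset[i] <- segs$frag_start[w] + (s$pos[i] - segs$seg_start[w])
      }
    }
  }
  called_key <- paste(frag, offset)
  planted_key <- paste(truth$snps$fragment, truth$snps$offset)

  # planted SNPs expected to pass the design filters, judged on the truth:
  # the population-secondary (lower-dosage) allele must be carried by at
  # least indep_min_genotypes genotypes, and both alleles must segregate
  ts <- truth$states[, calls$genotype_ids, drop = FALSE]
  het_c <- rowSums(ts == "het")
  alt_hom_c <- rowSums(ts == "hom_alt")
  ref_hom_c <- rowSums(ts == "hom_ref")
  alt_dose <- 2L * alt_hom_c + het_c
  ref_dose <- 2L * ref_hom_c + het_c
  sec_carriers <- ifelse(alt_dose <= ref_dose, het_c + alt_hom_c,
                         het_c + ref_hom_c)
  expected <- sec_carriers >= params$indep_min_genotypes &
    alt_dose > 0L & ref_dose > 0L
  n_expected <- sum(expected)
  recovered <- planted_key[expected] %in% called_key
  n_recovered <- sum(recovered)

  # genotype-state concordance at recovered planted SNPs
  n_cells <- 0L
  n_agree <- 0L
  mi <- match(called_key, planted_key)
  for (i in which(!is.na(mi))) {
    t_row <- truth$states[mi[i], calls$genotype_ids]
    c_row <- calls$states[i, ]
    # translate both to unordered base pairs
    t_pair <- switch_pair(truth$snps$ref[mi[i]], truth$snps$alt[mi[i]], t_row,
                          c("hom_ref", "het", "hom_alt"))
    c_pair <- switch_pair(s$primary[i], s$secondary[i], c_row,
                          c("hom_primary", "het", "hom_secondary"))
    ok <- c_row != "missing"
    n_cells <- n_cells + sum(ok)
    n_agree <- n_agree + sum(t_pair[ok] == c_pair[ok])
  }
  list(n_planted = nrow(truth$snps), n_expected = n_expected,
       n_recovered = n_recovered,
       recovery_pct = if (n_expected) 100 * n_recovered / n_expected else NA_real_,
       concordance_pct = if (n_cells) 100 * n_agree / n_cells else NA_real_,
       n_false_positives = sum(!(called_key %in% planted_key)),
       n_called = nrow(s))
}

# encode states as sorted base pairs, e.g. "A/G" (a, b are scalars)
switch_pair <- function(a, b, states, labels) {
  out <- rep(NA_character_, length(states))
  out[states == labels[1]] <- paste0(a, "/", a)
  out[states == labels[2]] <- paste0(min(a, b), "/", max(a, b))
  out[states == labels[3]] <- paste0(b, "/", b)
  out
}
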