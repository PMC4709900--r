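# Step 8: exports to numeric/HapMap/PLINK formats plus the modified Gower
# identity-by-state similarity used to recognise biological replicates.

#' Recode SNP calls as a numeric genotype matrix
#'
#' Primary homozygotes become 0, heterozygotes 0.5, secondary homozygotes
#' 1, unassigned genotypes `NA` -- the encoding diversity analyses in R
#' expect.
#'
#' @param calls An `snp_calls` object.
#' @return Numeric matrix (SNPs x genotypes) with rownames `ref_id_pos`.
#' @export
to_numeric_matrix <- function(calls) {
  map <- c(hom_primary = 0, het = 0.5, hom_secondary = 1, missing = NA_real_)
  matrix(map[calls$states], nrow = nrow(calls$states),
         ncol = length(calls$genotype_ids),
         dimnames = list(paste(calls$summary$ref_id, calls$summary$pos,
                               sep = "_"),
                         calls$genotype_ids))
}

#' @param path Output TSV path (missing values written as `NA`).
#' @rdname to_numeric_matrix
#' @export
write_numeric_matrix <- function(calls, path) {
  m <- to_numeric_matrix(calls)
  utils::write.table(data.frame(snp_id = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Export SNP calls as a HapMap table
#'
#' Standard 11 fixed columns (`rs#`, `alleles`, `chrom`, `pos`, `strand`,
#' then assembly/center/protLSID/assayLSID/panelLSID/QCcode as `NA`)
#' followed by one diploid base-pair column per genotype; heterozygotes are
#' written primary-then-secondary base, missing as `NN`.
#'
#' @param calls An `snp_calls` object.
#' @return A data.frame in HapMap layout.
#' @export
to_hapmap <- function(calls) {
  s <- calls$summary
  n <- nrow(s)
  geno <- matrix("NN", n, length(calls$genotype_ids),
                 dimnames = list(NULL, calls$genotype_ids))
  for (g in seq_along(calls$genotype_ids)) {
    st <- calls$states[, g]
    geno[st == "hom_primary", g] <- strrep(s$primary[st == "hom_primary"], 2L)
    geno[st == "hom_secondary", g] <- strrep(s$secondary[st == "hom_secondary"], 2L)
    geno[st == "het", g] <- paste0(s$primary[st == "het"], s$secondary[st == "het"])
  }
  fixed <- data.frame(
    `rs#` = paste(s$ref_id, s$pos, sep = "_"),
    alleles = paste(s$primary, s$secondary, sep = "/"),
    chrom = s$ref_id, pos = s$pos, strand = rep("+", n),
    `assembly#` = rep(NA_character_, n), center = rep(NA_character_, n),
    protLSID = rep(NA_character_, n), assayLSID = rep(NA_character_, n),
    panelLSID = rep(NA_character_, n), QCcode = rep(NA_character_, n),
    check.names = FALSE, stringsAsFactors = FALSE)
  cbind(fixed, as.data.frame(geno, stringsAsFactors = FALSE))
}

#' @rdname to_hapmap
#' @export
write_hapmap <- function(calls, path) {
  utils::write.table(to_hapmap(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Export SNP calls as PLINK transposed (.tped/.tfam) tables
#'
#' TPED rows carry chromosome, SNP id, genetic distance 0 and position,
#' then two allele columns per genotype (`0 0` for missing).  The TFAM uses
#' the genotype id for both family and individual id, unknown parents and
#' sex, phenotype -9.
#'
#' @param calls An `snp_calls` object.
#' @return A list with data.frames `tped` and `tfam`.
#' @export
to_plink_transposed <- function(calls) {
  s <- calls$summary
  n <- nrow(s)
  ng <- length(calls$genotype_ids)
  a1 <- matrix("0", n, ng)
  a2 <- matrix("0", n, ng)
  for (g in seq_len(ng)) {
    st <- calls$states[, g]
    a1[st == "hom_primary", g] <- s$primary[st == "hom_primary"]
    a2[st == "hom_primary", g] <- s$primary[st == "hom_primary"]
    a1[st == "het", g] <- s$primary[st == "het"]
    a2[st == "het", g] <- s$secondary[st == "het"]
    a1[st == "hom_secondary", g] <- s$secondary[st == "hom_secondary"]
    a2[st == "hom_secondary", g] <- s$secondary[st == "hom_secondary"]
  }
  tped <- data.frame(chrom = s$ref_id,
                     snp_id = paste(s$ref_id, s$pos, sep = "_"),
                     cm = rep(0L, n), pos = s$pos, stringsAsFactors = FALSE)
  for (g in seq_len(ng)) {
    tped[[paste0(calls$genotype_ids[g], "_1")]] <- a1[, g]
    tped[[paste0(calls$genotype_ids[g], "_2")]] <- a2[, g]
  }
  tfam <- data.frame(family = calls$genotype_ids, id = calls$genotype_ids,
                     father = 0L, mother = 0L, sex = 0L, phenotype = -9L,
                     stringsAsFactors = FALSE)
  list(tped = tped, tfam = tfam)
}

#' @param prefix Output path prefix; writes `<prefix>.tped` and
#'   `<prefix>.tfam`.
#' @rdname to_plink_transposed
#' @export
write_plink_transposed <- function(calls, prefix) {
  pl <- to_plink_transposed(calls)
  utils::write.table(pl$tped, paste0(prefix, ".tped"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(pl$tfam, paste0(prefix, ".tfam"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(tped = paste0(prefix, ".tped"), tfam = paste0(prefix, ".tfam")))
}

#' Modified Gower identity-by-state similarity
#'
#' For two genotype-state vectors over the same SNP list, each co-genotyped
#' locus scores 1 when the states agree, 0.5 when they differ by one allele
#' (heterozygote vs. homozygote) and 0 when they differ by both alleles
#' (opposite homozygotes); loci missing in either vector get weight 0.  The
#' similarity is the weighted mean of the locus scores.
#'
#' @param x,y Equal-length character vectors of states (`"hom_primary"`,
#'   `"het"`, `"hom_secondary"`, `"missing"`).
#' @return Similarity in `[0, 1]`.  Error when no locus is co-genotyped.
#' @export
gower_similarity <- function(x, y) {
  stopifnot(length(x) == length(y))
  w <- x != "missing" & y != "missing"
  if (!any(w)) stop("no co-genotyped SNPs shared by the two columns", call. = FALSE)
  num <- c(hom_primary = 0, het = 1, hom_secondary = 2)
  s <- 1 - abs(num[x[w]] - num[y[w]]) / 2
  sum(s) / sum(w)
}

#' Replicate-similarity report for two genotype columns
#'
#' @param calls An `snp_calls` object.
#' @param id_a,id_b Genotype ids to compare.
#' @return Named vector: `gower` (modified Gower similarity) and
#'   `pct_shared_calls` (percentage of exact genotype matches over
#'   co-genotyped SNPs).
#' @export
replicate_report <- function(calls, id_a, id_b) {
  ia <- match(id_a, calls$genotype_ids)
  ib <- match(id_b, calls$genotype_ids)
  if (is.na(ia) || is.na(ib)) {
    stop("unknown genotype id: ", if (is.na(ia)) id_a else id_b, call. = FALSE)
  }
  x <- calls$states[, ia]
  y <- calls$states[, ib]
  g <- gower_similarity(x, y)
  w <- x != "missing" & y != "missing"
  c(gower = g, pct_shared_calls = 100 * sum(x[w] == y[w]) / sum(w))
}
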