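# Synthetic GBS experiment generator: a restriction-fragment space with
# planted bi-allelic SNPs, diploid-style genotype states, and barcoded
# paired-end reads with uniform substitution errors -- everything needed
# to exercise the full workflow with a known truth.

#' Configuration for a synthetic GBS experiment
#'
#' Defaults describe a modest two-enzyme library: 150 bp paired-end reads,
#' 6-10 bp barcodes, fragment cores spanning 120-400 bp (so both the
#' overlap-merge and the stitch path are exercised), 40x mean depth per
#' genotype and fragment, and a 0.2 % per-base substitution error rate.
#'
#' @param n_fragments Number of restriction fragments.
#' @param fragment_len_range Range of fragment core lengths (bp).
#' @param n_genotypes Number of genotypes in the population.
#' @param n_snps Number of planted bi-allelic SNPs.
#' @param het_fraction Prior probability that a genotype is heterozygous at
#'   a SNP.
#' @param hom_alt_fraction Prior probability of the secondary-allele
#'   homozygote.
#' @param read_len Read length (bp).
#' @param mean_depth Mean read-pair count per genotype and fragment
#'   (Poisson).
#' @param error_rate Per-base substitution error probability.
#' @param barcode_set Optional character vector of barcodes (>= one per
#'   genotype + replicate); generated when `NULL`.
#' @param replicate_genotypes Genotype ids (e.g. `"G01"`) to sequence a
#'   second time from the same truth, as independent biological-replicate
#'   libraries; the replicate is named `<id>_rep`.
#' @param enzymes An [enzyme_pair()].
#' @param seed Integer seed fixing the full output stream.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_fragments = 300L, fragment_len_range = c(120L, 400L),
                              n_genotypes = 24L, n_snps = 150L,
                              het_fraction = 0.35, hom_alt_fraction = 0.20,
                              read_len = 150L, mean_depth = 40,
                              error_rate = 0.002, barcode_set = NULL,
                              replicate_genotypes = character(),
                              enzymes = enzyme_pair(), seed = 1L) {
  cfg <- list(n_fragments = as.integer(n_fragments),
              fragment_len_range = as.integer(fragment_len_range),
              n_genotypes = as.integer(n_genotypes), n_snps = as.integer(n_snps),
              het_fraction = het_fraction, hom_alt_fraction = hom_alt_fraction,
              read_len = as.integer(read_len), mean_depth = mean_depth,
              error_rate = error_rate, barcode_set = barcode_set,
              replicate_genotypes = replicate_genotypes,
              enzymes = enzymes, seed = as.integer(seed))
  stopifnot(cfg$n_fragments > 0, length(cfg$fragment_len_range) == 2,
            all(cfg$fragment_len_range > 0),
            cfg$fragment_len_range[1] <= cfg$fragment_len_range[2],
            cfg$n_genotypes > 0, cfg$n_snps >= 0,
            cfg$het_fraction >= 0, cfg$hom_alt_fraction >= 0,
            cfg$het_fraction + cfg$hom_alt_fraction <= 1,
            cfg$read_len >= 50, cfg$mean_depth > 0, cfg$error_rate >= 0,
            cfg$error_rate < 1)
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n, len) {
  vapply(len, function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                                collapse = ""), character(1))
}

# Random barcode set: lengths 6-10, same-length pairs kept >= 3 mismatches
# apart so one-mismatch demultiplexing stays unambiguous.
generate_barcodes <- function(n) {
  out <- character(0)
  lens <- integer(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 10000L) stop("failed to generate a barcode set", call. = FALSE)
    L <- sample(6:10, 1L)
    cand <- random_dna(1L, L)
    same <- out[lens == L]
    ok <- TRUE
    if (length(same)) {
      cm <- strsplit(cand, "")[[1]]
      for (s in same) {
        if (sum(cm != strsplit(s, "")[[1]]) < 3L) { ok <- FALSE; break }
      }
    }
    if (ok) { out <- c(out, cand); lens <- c(lens, L) }
  }
  out
}

other_bases <- function(b) {
  lapply(b, function(x) setdiff(c("A", "C", "G", "T"), x))
}

#' Simulate a barcoded paired-end GBS experiment
#'
#' Fragment cores are random sequence flanked (on the reads) by the
#' rare/common cut-site remnants; R1 reads carry barcode + rare remnant +
#' core prefix and read into the adapter when the fragment is short, R2
#' reads carry the common remnant + reverse-complemented core suffix.  SNP
#' alleles are drawn per read pair (heterozygotes emit each allele with
#' probability 1/2, and both mates of a pair carry the same molecule), the
#' pair count per genotype and fragment is Poisson(`mean_depth`), and
#' uniform substitution errors are applied across the entire read.  The
#' output stream is a deterministic function of `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param dir Optional output directory; when given, multiplexed
#'   `R1.fastq.gz`/`R2.fastq.gz`, the Barcode-ID file and truth tables are
#'   written there.
#' @return A list with `r1`, `r2` (read tables), `barcode_table`, and
#'   `truth` (list: `fragments`, `snps`, `states` matrix snp x genotype
#'   with entries `"hom_ref"`/`"het"`/`"hom_alt"`, `genotype_ids`,
#'   `read_counts`), plus `files` when `dir` was given.
#' @export
simulate_gbs <- function(config = simulation_config(), dir = NULL) {
  set.seed(config$seed)
  enz <- config$enzymes
  gids <- sprintf("G%02d", seq_len(config$n_genotypes))
  rep_src <- intersect(config$replicate_genotypes, gids)
  all_cols <- c(gids, if (length(rep_src)) paste0(rep_src, "_rep") else character(0))
  bcs <- config$barcode_set
  if (is.null(bcs)) bcs <- generate_barcodes(length(all_cols))
  if (length(bcs) < length(all_cols)) {
    stop("barcode set smaller than the number of genotypes (plus replicates)",
         call. = FALSE)
  }
  barcode_table <- data.frame(barcode = bcs[seq_along(all_cols)],
                              genotype_id = all_cols, stringsAsFactors = FALSE)
  validate_barcode_table(barcode_table)

  lenr <- config$fragment_len_range
  flen <- sample(seq(lenr[1], lenr[2]), config$n_fragments, replace = TRUE)
  cores <- random_dna(config$n_fragments, flen)
  fragments <- data.frame(fragment_id = sprintf("F%04d", seq_len(config$n_fragments)),
                          seq = cores, length = flen, stringsAsFactors = FALSE)

  # plant SNPs on positions covered by R1 or R2 even for stitched fragments
  snps <- data.frame(snp_id = character(), fragment = integer(), offset = integer(),
                     ref = character(), alt = character(), stringsAsFactors = FALSE)
  if (config$n_snps > 0) {
    cover <- 110L
    frag_pick <- sample(config$n_fragments, config$n_snps, replace = TRUE)
    offset <- integer(config$n_snps)
    for (i in seq_len(config$n_snps)) {
      L <- flen[frag_pick[i]]
      cand <- unique(c(seq_len(min(L, cover)),
                       seq(max(1L, L - cover + 1L), L)))
      offset[i] <- sample(cand, 1L)
    }
    dup <- duplicated(paste(frag_pick, offset))
    while (any(dup)) {
      for (i in which(dup)) {
        L <- flen[frag_pick[i]]
        cand <- unique(c(seq_len(min(L, cover)), seq(max(1L, L - cover + 1L), L)))
        offset[i] <- sample(cand, 1L)
      }
      dup <- duplicated(paste(frag_pick, offset))
    }
    ref <- substr(cores[frag_pick], offset, offset)
    alt <- vapply(other_bases(ref), function(o) sample(o, 1L), character(1))
    snps <- data.frame(snp_id = sprintf("S%04d", seq_len(config$n_snps)),
                       fragment = frag_pick, offset = offset, ref = ref,
                       alt = alt, stringsAsFactors = FALSE)
  }

  # true genotype states; replicate columns share their source's states
  pr <- c(1 - config$het_fraction - config$hom_alt_fraction,
          config$het_fraction, config$hom_alt_fraction)
  states <- matrix(sample(c("hom_ref", "het", "hom_alt"),
                          nrow(snps) * config$n_genotypes, replace = TRUE,
                          prob = pr),
                   nrow = nrow(snps), ncol = config$n_genotypes,
                   dimnames = list(snps$snp_id, gids))
  if (length(rep_src)) {
    states <- cbind(states, states[, rep_src, drop = FALSE])
    colnames(states) <- all_cols
  }

  adapter2 <- strrep(enz$adapter, 6L)   # read-through padding
  rc_common <- revcomp_chr(enz$common_remnant)
  r1_all <- vector("list", length(all_cols))
  r2_all <- vector("list", length(all_cols))
  read_counts <- integer(length(all_cols))
  for (g in seq_along(all_cols)) {
    bc <- barcode_table$barcode[g]
    npairs <- rpois(config$n_fragments, config$mean_depth)
    fragidx <- rep.int(seq_len(config$n_fragments), npairs)
    nreads <- length(fragidx)
    read_counts[g] <- nreads
    if (!nreads) {
      r1_all[[g]] <- empty_read_table()
      r2_all[[g]] <- empty_read_table()
      next
    }
    # apply homozygous-alt substitutions once per genotype...
    core_g <- cores
    gs <- states[, g]
    hom_alt <- which(gs == "hom_alt")
    for (i in hom_alt) {
      substr(core_g[snps$fragment[i]], snps$offset[i], snps$offset[i]) <- snps$alt[i]
    }
    core_read <- core_g[fragidx]
    # ...and heterozygous alleles per read pair (one molecule per pair)
    for (i in which(gs == "het")) {
      rows <- which(fragidx == snps$fragment[i])
      pick <- rows[runif(length(rows)) < 0.5]
      if (length(pick)) {
        substr(core_read[pick], snps$offset[i], snps$offset[i]) <- snps$alt[i]
      }
    }
    r1 <- substr(paste0(bc, enz$rare_remnant, core_read, rc_common, adapter2),
                 1L, config$read_len)
    r2 <- substr(paste0(enz$common_remnant, revcomp_chr(core_read),
                        revcomp_chr(paste0(bc, enz$rare_remnant)), adapter2),
                 1L, config$read_len)
    if (config$error_rate > 0) {
      r1 <- cpp_add_errors(r1, config$error_rate)
      r2 <- cpp_add_errors(r2, config$error_rate)
    }
    ids <- sprintf("sim_%s_%s_%d", all_cols[g],
                   fragments$fragment_id[fragidx], seq_len(nreads))
    qual <- strrep("I", nchar(r1))
    r1_all[[g]] <- data.frame(id = ids, seq = r1, qual = qual,
                              stringsAsFactors = FALSE)
    r2_all[[g]] <- data.frame(id = ids, seq = r2, qual = strrep("I", nchar(r2)),
                              stringsAsFactors = FALSE)
  }
  r1 <- do.call(rbind, r1_all)
  r2 <- do.call(rbind, r2_all)
  rownames(r1) <- rownames(r2) <- NULL
  truth <- list(fragments = fragments, snps = snps, states = states,
                genotype_ids = all_cols,
                read_counts = stats::setNames(read_counts, all_cols))
  out <- list(r1 = r1, r2 = r2, barcode_table = barcode_table, truth = truth,
              config = config)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(r1 = file.path(dir, "R1.fastq.gz"),
               r2 = file.path(dir, "R2.fastq.gz"),
               barcodes = file.path(dir, "barcodes.tsv"),
               fragments = file.path(dir, "truth_fragments.tsv"),
               snps = file.path(dir, "truth_snps.tsv"),
               states = file.path(dir, "truth_states.tsv"))
    write_fastq(r1, files["r1"], compress = TRUE)
    write_fastq(r2, files["r2"], compress = TRUE)
    write_barcode_table(barcode_table, files["barcodes"])
    utils::write.table(fragments, files["fragments"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(snps, files["snps"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(data.frame(snp_id = rownames(states), states,
                                  check.names = FALSE),
                       files["states"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$files <- files
  }
  out
}
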