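# End-to-end orchestration: raw multiplexed FASTQ to the final SNP
# genotyping matrix, equal to running the stage functions in sequence.

#' Run the full reference-free GBS SNP-calling workflow
#'
#' Stages: parse by barcode/cut-site, quality-trim, demultiplex; select the
#' most read-abundant genotype(s) and build the Mock Reference from their
#' merged/stitched reads; map every genotype's pairs back; pile up,
#' distill counts, assemble the master matrix; call SNPs and genotypes.
#' Entirely deterministic for fixed inputs.
#'
#' @param r1,r2 Read tables or FASTQ(.gz) paths holding synchronized raw
#'   mates.
#' @param barcode_table Barcode-ID data.frame or path to the two-column
#'   file.
#' @param enzymes An [enzyme_pair()].
#' @param params A [calling_params()].
#' @param mockref_genotypes Number of most read-abundant genotypes used to
#'   build the Mock Reference (default 1), or a character vector of
#'   genotype ids.
#' @param cluster_threshold Identity threshold for Mock Reference
#'   clustering.
#' @param reference Optional pre-built `MockReference` (or named sequence
#'   vector) to map against, skipping Stage 2.
#' @param max_edit_frac Mapper per-read mismatch fraction ceiling.
#' @param min_base_q Minimum base quality counted in pileups.
#' @param trim Named list overriding [quality_trim()] defaults
#'   (`window`, `min_q`, `lead_q`, `trail_q`, `min_len`).
#' @param output_dir Optional directory: demultiplexed FASTQ, Mock
#'   Reference FASTA, master matrix, final SNP matrix and a JSON manifest
#'   are written there.
#' @return A list of class `gbs_run`: `parse_stats`, `trim_stats`,
#'   `read_counts`, `mockref`, `alignment_stats`, `master`, `calls`.
#' @export
run_gbs_pipeline <- function(r1, r2, barcode_table, enzymes = enzyme_pair(),
                             params = calling_params(),
                             mockref_genotypes = 1L, cluster_threshold = 0.93,
                             reference = NULL, max_edit_frac = 0.07,
                             min_base_q = 0L, trim = list(),
                             output_dir = NULL) {
  if (is.character(r1)) r1 <- read_fastq(r1)
  if (is.character(r2)) r2 <- read_fastq(r2)
  if (is.character(barcode_table)) barcode_table <- read_barcode_table(barcode_table)

  parsed <- parse_read_pairs(r1, r2, barcode_table, enzymes)
  targs <- utils::modifyList(list(window = 4L, min_q = 30, lead_q = 30,
                                  trail_q = 30, min_len = 32L), trim)
  trimmed <- trim_read_pairs(parsed$pairs, targs$window, targs$min_q,
                             targs$lead_q, targs$trail_q, targs$min_len)
  by_g <- demultiplex_pairs(trimmed$pairs)
  read_counts <- vapply(by_g, nrow, integer(1))

  mockref <- reference
  if (is.null(mockref)) {
    sel <- if (is.character(mockref_genotypes)) {
      mockref_genotypes
    } else {
      select_mockref_genotypes(read_counts, mockref_genotypes)
    }
    merged <- lapply(by_g[sel], merge_or_stitch)
    mockref <- build_mock_reference(lapply(merged, `[[`, "seq"),
                                    selected = sel,
                                    threshold = cluster_threshold)
  }

  counts_list <- vector("list", length(by_g))
  names(counts_list) <- names(by_g)
  indel_pos <- list()
  aln_stats <- matrix(0L, length(by_g), 2L,
                      dimnames = list(names(by_g), c("total_pairs", "mapped_pairs")))
  for (g in names(by_g)) {
    al <- align_read_pairs(by_g[[g]], mockref, max_edit_frac = max_edit_frac)
    aln_stats[g, ] <- attr(al, "stats")
    pu <- make_pileup(al, mockref, min_base_q = min_base_q)
    indel_pos[[g]] <- pu[pu$indel_evidence, c("ref_id", "pos"), drop = FALSE]
    counts_list[[g]] <- pileup_to_counts(pu)
  }
  indel_union <- unique(do.call(rbind, indel_pos))
  master <- build_master_matrix(counts_list, indel_positions = indel_union)
  calls <- call_snps(master, params)

  run <- structure(list(parse_stats = parsed$stats, trim_stats = trimmed$stats,
                        read_counts = read_counts, mockref = mockref,
                        alignment_stats = aln_stats, master = master,
                        calls = calls, params = params),
                   class = "gbs_run")
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_parse_stats(parsed$stats, file.path(output_dir, "parse_stats.tsv"))
    write_demultiplexed(trimmed$pairs, trimmed$singletons,
                        file.path(output_dir, "demultiplexed"))
    write_mock_reference(mockref, output_dir)
    write_master_matrix(master, file.path(output_dir, "MasterMatrix.tsv"))
    write_snp_matrix(calls, file.path(output_dir, "SNPGenotypingMatrix.tsv"))
    manifest <- list(
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      package_version = as.character(utils::packageVersion("gbscallr")),
      n_genotypes = length(read_counts),
      read_counts = as.list(read_counts),
      mockref_centroids = nrow(mockref$centroids),
      master_positions = nrow(master$positions),
      snps_called = nrow(calls$summary),
      params = unclass(params))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  run
}

#' @export
print.gbs_run <- function(x, ...) {
  cat("gbs_run:\n")
  cat("  pairs parsed/retained:", x$parse_stats["total_pairs"], "/",
      x$parse_stats["retained"], "\n")
  cat("  genotypes:", length(x$read_counts), "| Mock Reference centroids:",
      nrow(x$mockref$centroids), "\n")
  cat("  master-matrix positions:", nrow(x$master$positions),
      "| SNPs called:", nrow(x$calls$summary), "\n")
  invisible(x)
}
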