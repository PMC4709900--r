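Package: gbscallr
Title: Reference-Free SNP Calling and Genotyping for
    Genotyping-by-Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A self-contained workflow for calling SNPs in multiplexed,
    paired-end genotyping-by-sequencing (GBS) libraries without a reference
    genome. Raw reads are parsed by barcode and restriction cut-site,
    quality-trimmed, and demultiplexed; overlapping mates are merged and
    long fragments stitched; the resulting reads are greedily clustered
    into a non-redundant "Mock Reference" of centroid sequences; reads are
    mapped back with pair-proper, unique-hit semantics; and per-genotype
    base-call pileups are distilled into a population master matrix from
    which bi-allelic SNPs are called with depth-based genotyping rules and
    population-level filters. Includes a synthetic GBS read simulator with
    truth tables, mpileup-text ingestion for externally aligned data, a
    modified Gower identity-by-state similarity for replicate detection,
    and exporters to numeric, HapMap and PLINK transposed formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
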