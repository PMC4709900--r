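# Small fixture builders shared across test files.

fixture_enzymes <- function() enzyme_pair()

fixture_barcodes <- function() {
  data.frame(barcode = c("ACGTAC", "TTGGCCAA", "GATCGATCGA"),
             genotype_id = c("gA", "gB", "gC"), stringsAsFactors = FALSE)
}

# A raw read pair for a given fragment core, mimicking the simulator's read
# model (barcode + rare remnant + core ... adapter read-through).
fixture_raw_pair <- function(core, barcode, enz = fixture_enzymes(),
                             read_len = 150L) {
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  pad <- strrep(enz$adapter, 6L)
  r1 <- substr(paste0(barcode, enz$rare_remnant, core, rc(enz$common_remnant),
                      pad), 1L, read_len)
  r2 <- substr(paste0(enz$common_remnant, rc(core),
                      rc(paste0(barcode, enz$rare_remnant)), pad), 1L, read_len)
  list(r1 = data.frame(id = "p1", seq = r1, qual = strrep("I", nchar(r1)),
                       stringsAsFactors = FALSE),
       r2 = data.frame(id = "p1", seq = r2, qual = strrep("I", nchar(r2)),
                       stringsAsFactors = FALSE))
}

# Read pairs taken directly from a fragment's two ends (already parsed).
fixture_fragment_pair <- function(fragment, read_len = 150L) {
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  L <- nchar(fragment)
  s1 <- substr(fragment, 1L, min(read_len, L))
  s2 <- rc(substr(fragment, max(1L, L - read_len + 1L), L))
  data.frame(seq1 = s1, qual1 = strrep("I", nchar(s1)),
             seq2 = s2, qual2 = strrep("I", nchar(s2)),
             stringsAsFactors = FALSE)
}

# A small simulated experiment reused by several files (computed once).
fixture_small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_fragments = 30L, n_genotypes = 6L,
                               n_snps = 15L, mean_depth = 30,
                               error_rate = 0.002, seed = 42L)
      cache <<- list(cfg = cfg, sim = simulate_gbs(cfg))
    }
    cache
  }
})

# A hand-sized master matrix: depth array from a list of per-genotype
# A/C/G/T rows.
fixture_master <- function(ref_base, cells, ref_id = "c1", pos = 10L) {
  ng <- length(cells)
  depths <- array(0L, dim = c(1L, ng, 4L),
                  dimnames = list(NULL, names(cells), c("A", "C", "G", "T")))
  for (g in seq_len(ng)) depths[1, g, ] <- cells[[g]]
  structure(list(positions = data.frame(ref_id = ref_id, pos = pos,
                                        ref_base = ref_base,
                                        stringsAsFactors = FALSE),
                 depths = depths, genotype_ids = names(cells)),
            class = "master_matrix")
}
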