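# Step 7: allele ranking, SNP filters, depth-based genotyping, and the
# final genotyping matrix.

test_that("allele ranking orders by population depth with A<C<G<T tie-break", {
  mm <- fixture_master("G", list(g1 = c(2L, 0L, 9L, 0L), g2 = c(3L, 0L, 8L, 5L)))
  r <- allele_ranking(mm)
  expect_equal(r$primary, "G")     # 17
  expect_equal(r$secondary, "A")   # 5 vs T 5: tie broken A first
  expect_equal(r$tertiary, "T")
  expect_equal(r$quaternary, "C")
  expect_equal(c(r$d1, r$d2, r$d3, r$d4), c(17L, 5L, 5L, 0L))
})

test_that("the independence filter needs the secondary allele at depth in >=3 genotypes", {
  p <- calling_params()
  mk <- function(a_depths) {
    cells <- lapply(a_depths, function(a) c(a, 0L, 40L, 0L))
    names(cells) <- sprintf("g%d", seq_along(a_depths))
    fixture_master("G", cells)
  }
  expect_true(independence_filter(mk(c(3L, 3L, 3L, 0L)), params = p))
  expect_false(independence_filter(mk(c(3L, 3L, 0L, 0L)), params = p))
  expect_false(independence_filter(mk(rep(2L, 10)), params = p))   # depth 2 never
  # pooled alternative reading
  pp <- calling_params(indep_pooled = TRUE)
  expect_true(independence_filter(mk(rep(2L, 10)), params = pp))
})

test_that("altStrength is the printed formula with a strict 0.90 boundary", {
  p <- calling_params()
  mk_rank <- function(d2, d3, d4) {
    data.frame(primary = "G", secondary = "A", tertiary = "C",
               quaternary = "T", d1 = 1000L, d2 = d2, d3 = d3, d4 = d4)
  }
  expect_true(alt_strength_filter(mk_rank(95L, 5L, 0L), p))    # 0.95
  expect_false(alt_strength_filter(mk_rank(9L, 1L, 0L), p))    # exactly 0.90
  expect_true(alt_strength_filter(mk_rank(10L, 0L, 0L), p))    # 1.0
  expect_false(alt_strength_filter(mk_rank(0L, 0L, 0L), p))    # monomorphic
  # agreement with direct evaluation on random depth triples
  set.seed(2)
  d <- matrix(sample(0:60, 3 * 10000, replace = TRUE), ncol = 3)
  rank <- data.frame(primary = "G", secondary = "A", tertiary = "C",
                     quaternary = "T", d1 = 1000L,
                     d2 = pmax(d[, 1], d[, 2], d[, 3]),
                     d3 = apply(d, 1, function(x) sort(x, decreasing = TRUE)[2]),
                     d4 = pmin(d[, 1], d[, 2], d[, 3]))
  got <- alt_strength_filter(rank, p)
  direct <- ifelse(rank$d2 + rank$d3 + rank$d4 > 0,
                   rank$d2 / (rank$d2 + rank$d3 + rank$d4) > 0.90, FALSE)
  expect_equal(got, direct)
})

test_that("genotype calls reproduce the published boundary cases", {
  p <- calling_params()
  expect_equal(call_genotype(132L, 5L, p), "missing")   # ratio 0.038 <= 0.1
  expect_equal(call_genotype(0L, 4L, p), "missing")     # depth 4 < 11
  expect_equal(call_genotype(11L, 0L, p), "hom_primary")
  expect_equal(call_genotype(10L, 0L, p), "missing")
  expect_equal(call_genotype(48L, 1L, p), "hom_primary")
  expect_equal(call_genotype(47L, 1L, p), "missing")
  expect_equal(call_genotype(20L, 10L, p), "het")       # 0.5 > 0.1, both >= 3
  expect_equal(call_genotype(0L, 11L, p), "hom_secondary")
  expect_equal(call_genotype(1L, 48L, p), "hom_secondary")
  # ratio exactly 0.1 must not call a heterozygote ("must exceed")
  expect_equal(call_genotype(30L, 3L, p), "missing")
})

test_that("the caller matches a rule-table oracle on the exhaustive depth grid", {
  grid <- expand.grid(p = 0:60, s = 0:60)
  t0 <- Sys.time()
  got <- call_genotype(grid$p, grid$s)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)
  exp <- mapply(oracle_call, grid$p, grid$s)
  expect_equal(got, unname(exp))
})

test_that("population filters cull on missingness and average depth bounds", {
  p <- calling_params()
  sm <- data.frame(pct_genotyped = c(100 * 35 / 48, 90, 90, 90, 75),
                   avg_depth = c(70, 4, 200, 70, 70))
  expect_equal(population_filters(sm, p), c(FALSE, FALSE, FALSE, TRUE, TRUE))
})

test_that("call_snps drops monomorphic rows and keeps Fig-2-consistent summaries", {
  # rows: a clean bi-allelic SNP, a monomorphic position, a tri-allelic one
  cells_snp <- list(g1 = c(0L, 0L, 40L, 0L), g2 = c(18L, 0L, 22L, 0L),
                    g3 = c(40L, 0L, 0L, 0L), g4 = c(5L, 0L, 36L, 1L))
  cells_mono <- list(g1 = c(0L, 0L, 30L, 0L), g2 = c(0L, 0L, 35L, 0L),
                     g3 = c(0L, 0L, 31L, 0L), g4 = c(0L, 0L, 29L, 0L))
  cells_tri <- list(g1 = c(30L, 8L, 22L, 0L), g2 = c(25L, 7L, 30L, 0L),
                    g3 = c(28L, 6L, 21L, 0L), g4 = c(30L, 5L, 20L, 0L))
  gids <- names(cells_snp)
  depths <- array(0L, dim = c(3, 4, 4),
                  dimnames = list(NULL, gids, c("A", "C", "G", "T")))
  for (g in 1:4) {
    depths[1, g, ] <- cells_snp[[g]]
    depths[2, g, ] <- cells_mono[[g]]
    depths[3, g, ] <- cells_tri[[g]]
  }
  master <- structure(list(positions = data.frame(ref_id = "c1",
                                                  pos = c(10L, 20L, 30L),
                                                  ref_base = "G",
                                                  stringsAsFactors = FALSE),
                           depths = depths, genotype_ids = gids),
                      class = "master_matrix")
  calls <- call_snps(master, calling_params())
  # only the bi-allelic SNP row survives: the monomorphic row has zero
  # secondary depth and the tri-allelic row fails altStrength (93/119)
  expect_equal(calls$summary$pos, 10L)
  expect_equal(calls$summary$primary, "G")
  expect_equal(calls$summary$secondary, "A")
  expect_equal(unname(calls$states[1, ]),
               c("hom_primary", "het", "hom_secondary", "het"))
  # columns 8-10 recount exactly from the per-genotype calls
  expect_equal(calls$summary$n_hom_primary, 1L)
  expect_equal(calls$summary$n_het, 2L)
  expect_equal(calls$summary$n_hom_secondary, 1L)
  expect_equal(calls$summary$pct_genotyped, 100)
  expect_equal(calls$summary$avg_depth, mean(c(40, 40, 40, 42)))
})

test_that("stricter parameters never increase the retained SNP count", {
  fx <- fixture_small_sim()
  run <- run_gbs_pipeline(fx$sim$r1, fx$sim$r2, fx$sim$barcode_table)
  n0 <- nrow(run$calls$summary)
  for (p in list(calling_params(alt_strength = 0.97),
                 calling_params(indep_min_depth = 10L),
                 calling_params(indep_min_genotypes = 5L),
                 calling_params(min_called_frac = 0.95))) {
    expect_lte(nrow(call_snps(run$master, p)$summary), n0)
  }
})

test_that("identical master matrix and parameters give byte-identical output", {
  fx <- fixture_small_sim()
  run <- run_gbs_pipeline(fx$sim$r1, fx$sim$r2, fx$sim$barcode_table)
  td <- withr::local_tempdir()
  f1 <- file.path(td, "a.tsv")
  f2 <- file.path(td, "b.tsv")
  write_snp_matrix(call_snps(run$master, calling_params()), f1)
  write_snp_matrix(call_snps(run$master, calling_params()), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_gt(nrow(run$calls$summary), 0L)
  # cell grammar: state|primary/secondary with '-' for missing
  lines <- readLines(f1)
  expect_match(lines[2], "\\t[PHS-]\\|\\d+/\\d+", perl = TRUE)
})
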