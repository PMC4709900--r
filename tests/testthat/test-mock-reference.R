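# Stage 2: PE merging, stitching, identity, clustering, Mock Reference.

test_that("overlapping mates reconstruct the fragment exactly", {
  set.seed(3)
  frag <- random_seq(250)
  pr <- fixture_fragment_pair(frag)          # two 150 bp reads, 50 bp overlap
  m <- merge_read_pairs(pr)
  expect_equal(m$status, "assembled")
  expect_equal(m$seq, frag)
  expect_equal(nchar(m$qual), 250L)

  # 350 bp fragment: no overlap possible
  m2 <- merge_read_pairs(fixture_fragment_pair(random_seq(350)))
  expect_equal(m2$status, "unmerged")

  # constructed 9 bp perfect overlap stays unmerged (below the >= 10 bp rule)
  frag9 <- random_seq(2 * 60 - 9)
  pr9 <- fixture_fragment_pair(frag9, read_len = 60L)
  expect_equal(merge_read_pairs(pr9)$status, "unmerged")
  # ...but 10 bp merges
  frag10 <- random_seq(2 * 60 - 10)
  pr10 <- fixture_fragment_pair(frag10, read_len = 60L)
  m10 <- merge_read_pairs(pr10)
  expect_equal(m10$status, "assembled")
  expect_equal(m10$seq, frag10)
})

test_that("mismatching overlap columns take the higher-quality base", {
  s1 <- paste0(strrep("CGTGC", 4), "ACCGTGGCTA")
  s2rc <- paste0("ACCGTGGCTT", strrep("GTCCG", 4))  # 1 mismatch in the overlap
  pr <- data.frame(seq1 = s1, qual1 = paste0(strrep("I", 29), "#"),
                   seq2 = chartr("ACGT", "TGCA",
                                 paste(rev(strsplit(s2rc, "")[[1]]),
                                       collapse = "")),
                   qual2 = strrep("I", 30), stringsAsFactors = FALSE)
  m <- merge_read_pairs(pr, max_mismatch_frac = 0.1)
  expect_equal(m$status, "assembled")
  # R1's low-quality 'A' at the mismatch column loses to R2's Q40 'T'
  expect_equal(substr(m$seq, 30, 30), "T")
  expect_equal(substr(m$qual, 30, 30), "I")
})

test_that("short merges are discarded, not kept", {
  frag <- random_seq(20)
  pr <- fixture_fragment_pair(frag, read_len = 20L)
  expect_equal(merge_read_pairs(pr)$status, "discarded")
})

test_that("stitching joins unmerged mates with a Phred-40 20-A junction", {
  pr <- data.frame(seq1 = random_seq(90), qual1 = strrep("E", 90),
                   seq2 = random_seq(90), qual2 = strrep("E", 90),
                   stringsAsFactors = FALSE)
  st <- stitch_read_pairs(pr)
  expect_equal(st$status, "stitched")
  expect_equal(nchar(st$seq), 200L)
  expect_equal(substr(st$seq, 91, 110), strrep("A", 20))
  expect_equal(substr(st$qual, 91, 110), strrep("I", 20))
  expect_equal(substr(st$seq, 1, 90), pr$seq1)
  expect_equal(substr(st$seq, 111, 200),
               chartr("ACGT", "TGCA",
                      paste(rev(strsplit(pr$seq2, "")[[1]]), collapse = "")))
  # a 20 bp mate is too short
  pr2 <- data.frame(seq1 = random_seq(90), qual1 = strrep("I", 90),
                    seq2 = random_seq(20), qual2 = strrep("I", 20))
  expect_equal(stitch_read_pairs(pr2)$status, "discarded")
})

test_that("merge and stitch outcomes partition the input pairs", {
  set.seed(8)
  frags <- vapply(sample(120:400, 40, replace = TRUE), random_seq, character(1))
  prs <- do.call(rbind, lapply(frags, fixture_fragment_pair))
  ms <- merge_or_stitch(prs)
  cnt <- attr(ms, "counts")
  expect_equal(cnt[["assembled"]] + cnt[["stitched"]] + cnt[["discarded"]],
               cnt[["pairs"]])
  expect_equal(nrow(ms), cnt[["assembled"]] + cnt[["stitched"]])
})

test_that("pairwise identity matches hand-derived and oracle values", {
  a <- strrep("ACGT", 25)
  expect_equal(pairwise_identity(a, a), 1.0)
  # two mismatches in 32-mers: 30/32, co-clusterable at 0.93
  set.seed(5)
  b <- random_seq(32)
  b2 <- mutate_seq(b, c(6, 21))
  expect_equal(pairwise_identity(b, b2), 30 / 32)
  expect_true(pairwise_identity(b, b2) >= 0.93)
  # single internal insertion: 100/101
  x <- random_seq(100)
  xi <- paste0(substr(x, 1, 47), "G", substr(x, 48, 100))
  expect_equal(pairwise_identity(x, xi), 100 / 101)
  # symmetry and oracle agreement on random pairs
  for (i in 1:20) {
    u <- random_seq(sample(40:90, 1))
    v <- mutate_seq(u, sample(nchar(u), sample(0:6, 1)))
    if (runif(1) < 0.5) v <- paste0(substr(v, 1, 20), substr(v, 22, nchar(v)))
    expect_equal(pairwise_identity(u, v), pairwise_identity(v, u))
    expect_equal(pairwise_identity(u, v), oracle_identity(u, v))
  }
})

test_that("greedy clustering is first-fit over length-then-lexicographic order", {
  set.seed(9)
  s <- random_seq(100)
  cl <- greedy_cluster(rep(s, 10))
  expect_equal(nrow(cl$centroids), 1L)
  expect_equal(cl$centroids$member_count, 10L)
  expect_equal(cl$centroids$seq, s)

  # two 100-mers at 85 % identity split at threshold 0.93
  t <- mutate_seq(s, sample(100, 15))
  expect_lt(pairwise_identity(s, t), 0.93)
  cl2 <- greedy_cluster(c(s, t), 0.93)
  expect_equal(nrow(cl2$centroids), 2L)

  # 32-mers within two mismatches co-cluster at 0.93
  b <- random_seq(32)
  cl3 <- greedy_cluster(c(b, mutate_seq(b, c(3, 30))), 0.93)
  expect_equal(nrow(cl3$centroids), 1L)

  # partition: member counts sum to the input size
  reads <- c(rep(s, 4), rep(t, 3), random_seq(80))
  cl4 <- greedy_cluster(reads)
  expect_equal(sum(cl4$centroids$member_count), length(reads))
  expect_equal(length(cl4$assignment), length(reads))
  expect_true(all(cl4$assignment %in% cl4$centroids$id))
})

test_that("raising the identity threshold never decreases the centroid count", {
  set.seed(13)
  base <- random_seq(120)
  reads <- c(vapply(1:12, function(i) mutate_seq(base, sample(120, i)),
                    character(1)),
             vapply(1:5, function(i) random_seq(120), character(1)))
  counts <- vapply(c(0.80, 0.88, 0.93, 0.97, 1.0),
                   function(th) nrow(greedy_cluster(reads, th)$centroids),
                   integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("the Mock Reference collects centroids with invertible offsets", {
  set.seed(21)
  frags <- c(random_seq(200), random_seq(240), random_seq(260))
  reads <- rep(frags, times = c(5, 4, 3))
  mr <- build_mock_reference(list(gA = reads), selected = "gA")
  expect_s3_class(mr, "MockReference")
  expect_equal(nrow(mr$centroids), 3L)
  expect_setequal(mr$centroids$seq, frags)
  expect_equal(nchar(mr$genome_seq), sum(mr$centroids$length))
  expect_equal(sum(mr$centroids$member_count), length(reads))

  # offsets invert: genome -> centroid-local -> genome is the identity
  pos <- c(1L, 150L, 201L, 250L, nchar(mr$genome_seq))
  loc <- genome_to_centroid(mr, pos)
  expect_equal(centroid_to_genome(mr, loc$centroid_id, loc$local_pos), pos)
  # every centroid's offset interval slices its own sequence out of the genome
  for (i in seq_len(nrow(mr$centroids))) {
    expect_equal(substr(mr$genome_seq, mr$offsets$start[i], mr$offsets$end[i]),
                 mr$centroids$seq[i])
  }

  # two genotypes sharing fragments collapse to the same centroid count
  mr2 <- build_mock_reference(list(gA = reads, gB = reads))
  expect_equal(nrow(mr2$centroids), 3L)
  expect_true(all(vapply(mr2$centroids$source_genotypes,
                         function(x) identical(x, c("gA", "gB")), logical(1))))

  expect_error(build_mock_reference(list(gA = reads), selected = character()),
               "no genotypes")
})

test_that("Mock Reference FASTA files round-trip in order", {
  set.seed(22)
  reads <- c(rep(random_seq(150), 3), rep(random_seq(180), 2))
  mr <- build_mock_reference(list(g = reads))
  td <- withr::local_tempdir()
  paths <- write_mock_reference(mr, td)
  back <- read_mock_reference(paths[["clusters"]])
  expect_equal(back$centroids$id, mr$centroids$id)
  expect_equal(back$centroids$seq, mr$centroids$seq)
  expect_equal(back$genome_seq, mr$genome_seq)
  expect_equal(back$offsets, mr$offsets)
  genome <- read_fasta(paths[["genome"]])
  expect_equal(unname(genome), mr$genome_seq)
})

test_that("error-free reads rebuild fragments exactly (merge and stitch paths)", {
  cfg <- simulation_config(n_fragments = 15L, n_genotypes = 2L, n_snps = 0L,
                           mean_depth = 15, error_rate = 0, seed = 99L)
  sim <- simulate_gbs(cfg)
  parsed <- parse_read_pairs(sim$r1, sim$r2, sim$barcode_table)
  by_g <- demultiplex_pairs(parsed$pairs)
  ms <- merge_or_stitch(by_g[[1]])
  frags <- sim$truth$fragments$seq
  for (i in which(ms$origin == "assembled")) {
    expect_true(ms$seq[i] %in% frags)
  }
  for (i in which(ms$origin == "stitched")) {
    parts <- strsplit(ms$seq[i], "A{20}")[[1]]
    frag <- frags[vapply(frags, function(f) startsWith(f, parts[1]), logical(1))]
    expect_length(frag, 1L)
  }
})
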