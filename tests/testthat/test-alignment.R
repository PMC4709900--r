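# Stage 3: seed-and-extend mapping, pileups, and mpileup-text ingestion.

make_refs <- function() {
  set.seed(17)
  stats::setNames(c(random_seq(300), random_seq(280)), c("c1", "c2"))
}

test_that("mapping finds unique loci and refuses ties", {
  refs <- make_refs()
  # read equal to a unique centroid substring maps at the construction offset
  pr <- data.frame(id = "p", seq1 = substr(refs["c1"], 41, 160),
                   qual1 = strrep("I", 120),
                   seq2 = chartr("ACGT", "TGCA",
                                 paste(rev(strsplit(substr(refs["c1"], 161, 280),
                                                    "")[[1]]), collapse = "")),
                   qual2 = strrep("I", 120), stringsAsFactors = FALSE)
  al <- align_read_pairs(pr, refs)
  expect_equal(nrow(al), 2L)
  expect_equal(al$ref_id, c("c1", "c1"))
  expect_equal(al$pos, c(41L, 161L))
  expect_equal(al$strand, c("+", "-"))
  expect_equal(al$edits, c(0L, 0L))

  # a read present in both centroids is a tie, so the pair is dropped
  dup <- substr(refs["c1"], 1, 100)
  refs2 <- c(refs, c3 = paste0(dup, substr(random_seq(200), 1, 200)))
  pr2 <- pr
  pr2$seq1 <- dup
  pr2$qual1 <- strrep("I", 100)
  al2 <- align_read_pairs(pr2, refs2)
  expect_equal(nrow(al2), 0L)
})

test_that("mismatched reads map to the right locus with the right edit count", {
  refs <- make_refs()
  set.seed(31)
  for (i in 1:10) {
    off <- sample(1:150, 1)
    read <- mutate_seq(substr(refs[["c2"]], off, off + 119), sample(120, 2))
    got <- gbscallr:::cpp_map_reads(read, unname(refs), 20L, 10L, 0.07,
                                    list(NULL, NULL))
    exp <- oracle_map(read, unname(refs))
    expect_equal(got$ref, exp$best$ref)
    expect_equal(got$pos, exp$best$pos)
    expect_equal(got$edits, exp$best$mm)
    expect_equal(got$edits, 2L)
  }
})

test_that("alignments may not cross a stitched-read A-junction", {
  left <- random_seq(100)
  right <- random_seq(100)
  stitched <- stats::setNames(paste0(left, strrep("A", 20), right), "st1")
  spanning <- substr(stitched, 91, 140)   # 10 left + 20 A + 20 right
  got <- gbscallr:::cpp_map_reads(spanning, unname(stitched), 20L, 10L, 0.07,
                                  list(gbscallr:::find_a_runs(stitched)))
  expect_equal(got$ref, 0L)
  within_arm <- substr(stitched, 31, 90)
  got2 <- gbscallr:::cpp_map_reads(within_arm, unname(stitched), 20L, 10L, 0.07,
                                   list(gbscallr:::find_a_runs(stitched)))
  expect_equal(got2$pos, 31L)
})

test_that("pairs mapping to different centroids or same strand are rejected", {
  refs <- make_refs()
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  cross <- data.frame(id = "x", seq1 = substr(refs["c1"], 1, 100),
                      qual1 = strrep("I", 100),
                      seq2 = rc(substr(refs["c2"], 100, 199)),
                      qual2 = strrep("I", 100), stringsAsFactors = FALSE)
  expect_equal(nrow(align_read_pairs(cross, refs)), 0L)
  same_strand <- data.frame(id = "y", seq1 = substr(refs["c1"], 1, 100),
                            qual1 = strrep("I", 100),
                            seq2 = substr(refs["c1"], 101, 200),
                            qual2 = strrep("I", 100), stringsAsFactors = FALSE)
  expect_equal(nrow(align_read_pairs(same_strand, refs)), 0L)
})

test_that("pileup counts bases per position and counts mate overlaps once", {
  ref <- stats::setNames(strrep("ACGT", 25), "r")
  mk_al <- function(pair_id, mate, pos, seq, qual = strrep("I", nchar(seq)),
                    cigar = paste0(nchar(seq), "M")) {
    data.frame(read_id = paste0("p", pair_id), pair_id = pair_id, mate = mate,
               ref_id = "r", pos = pos, strand = "+", cigar = cigar,
               edits = 0L, mate_pos = pos, is_unique = TRUE, seq = seq,
               qual = qual, stringsAsFactors = FALSE)
  }
  # 5 reads A + 3 reads C at position 1
  al <- rbind(do.call(rbind, lapply(1:5, function(i) mk_al(i, 1L, 1L, "A"))),
              do.call(rbind, lapply(6:8, function(i) mk_al(i, 1L, 1L, "C"))))
  pu <- make_pileup(al, ref)
  expect_equal(pu[pu$pos == 1, c("A", "C", "G", "T")],
               data.frame(A = 5L, C = 3L, G = 0L, T = 0L))
  expect_equal(pu$ref_base[pu$pos == 1], "A")

  # overlapping mates of one pair count once; higher quality wins
  al2 <- rbind(mk_al(1, 1L, 1L, "AAGT", qual = "III#"),
               mk_al(1, 2L, 4L, "CCGT"))   # overlap at position 4: T(#) vs C(I)
  pu2 <- make_pileup(al2, ref)
  expect_equal(sum(pu2$A + pu2$C + pu2$G + pu2$T), 7L)  # 4 + 4 - 1 overlap
  expect_equal(pu2$C[pu2$pos == 4], 1L)                 # the Q40 'C' won
  expect_equal(pu2$T[pu2$pos == 4], 0L)

  # a position inside a deletion carries indel evidence
  al3 <- mk_al(1, 1L, 10L, "ACGTACGT", cigar = "4M2D4M")
  pu3 <- make_pileup(al3, ref)
  expect_true(all(pu3$indel_evidence[pu3$pos %in% c(14, 15)]))
  expect_false(any(pu3$indel_evidence[pu3$pos %in% c(10, 11, 12, 13)]))
  # insertion flags its flanking positions
  al4 <- mk_al(1, 1L, 20L, "ACGTAACGT", cigar = "4M1I4M")
  pu4 <- make_pileup(al4, ref)
  expect_true(all(pu4$indel_evidence[pu4$pos %in% c(23, 24)]))

  # base-quality floor drops low-quality bases
  al5 <- mk_al(1, 1L, 1L, "ACGT", qual = "I#II")
  pu5 <- make_pileup(al5, ref, min_base_q = 20L)
  expect_equal(nrow(pu5), 3L)
})

test_that("the mpileup dialect is parsed exactly", {
  td <- withr::local_tempdir()
  f <- file.path(td, "ex.pileup")
  writeLines(c(
    "c1\t10\tG\t4\t..,,\tIIII",
    "c1\t11\tG\t5\t.,AA.\tIIIII",
    "c1\t12\tT\t3\t.+2AG..\tIII",
    "c1\t13\tA\t6\t^I..$,,t.\tIIIIII",
    "c1\t14\tC\t3\t.,*-1a\tIII",
    "c1\t15\tN\t2\t.,\tII"), f)
  pu <- read_pileup(f)
  expect_equal(unlist(pu[pu$pos == 10, c("A", "C", "G", "T")], use.names = FALSE),
               c(0L, 0L, 4L, 0L))
  expect_equal(unlist(pu[pu$pos == 11, c("A", "C", "G", "T")], use.names = FALSE),
               c(2L, 0L, 3L, 0L))
  expect_equal(unlist(pu[pu$pos == 12, c("A", "C", "G", "T")], use.names = FALSE),
               c(0L, 0L, 0L, 3L))
  expect_true(pu$indel_evidence[pu$pos == 12])
  # '^I' consumed its mapq char; '$' ignored; 't' case-folded
  expect_equal(unlist(pu[pu$pos == 13, c("A", "C", "G", "T")], use.names = FALSE),
               c(5L, 0L, 0L, 1L))
  # '*' and '-1a' mark indel evidence
  expect_true(pu$indel_evidence[pu$pos == 14])
  expect_equal(pu$C[pu$pos == 14], 2L)
  # reference-base N: dots resolve to nothing countable, row dropped
  expect_false(15 %in% pu$pos)
})

test_that("malformed mpileup text errors with the line number", {
  td <- withr::local_tempdir()
  f1 <- file.path(td, "bad1.pileup")
  writeLines(c("c1\t10\tG\t4\t..,,\tIIII", "c1\t11\tG\t4\t..+\tIIII"), f1)
  expect_error(read_pileup(f1), "line 2")
  f2 <- file.path(td, "bad2.pileup")
  writeLines("c1\t10\tG\t5\t..,,\tIIII", f2)   # depth says 5, string has 4
  expect_error(read_pileup(f2), "line 1.*4.*5")
  f3 <- file.path(td, "bad3.pileup")
  writeLines("c1\t10\tG\t2\t.^\tII", f3)
  expect_error(read_pileup(f3), "line 1")
})

test_that("built-in pileup survives an mpileup-text round trip", {
  fx <- fixture_small_sim()
  parsed <- parse_read_pairs(fx$sim$r1, fx$sim$r2, fx$sim$barcode_table)
  by_g <- demultiplex_pairs(parsed$pairs)
  mr <- build_mock_reference(list(g = merge_or_stitch(by_g[[1]])$seq))
  al <- align_read_pairs(by_g[[1]], mr)
  pu <- make_pileup(al, mr)
  td <- withr::local_tempdir()
  f <- file.path(td, "roundtrip.pileup")
  write_pileup(pu, f)
  back <- read_pileup(f)
  expect_equal(back$A, pu$A)
  expect_equal(back$C, pu$C)
  expect_equal(back$G, pu$G)
  expect_equal(back$T, pu$T)
  expect_equal(back$pos, pu$pos)
  expect_equal(back$indel_evidence, pu$indel_evidence)
})

test_that("SAM export is minimally valid and field-complete", {
  refs <- make_refs()
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  pr <- data.frame(id = "p1 extra", seq1 = substr(refs["c1"], 11, 110),
                   qual1 = strrep("I", 100),
                   seq2 = rc(substr(refs["c1"], 121, 220)),
                   qual2 = strrep("I", 100), stringsAsFactors = FALSE)
  al <- align_read_pairs(pr, refs)
  td <- withr::local_tempdir()
  f <- file.path(td, "out.sam")
  write_sam(al, refs, f)
  lines <- readLines(f)
  expect_true(startsWith(lines[1], "@HD"))
  expect_equal(sum(startsWith(lines, "@SQ")), 2L)
  body <- lines[!startsWith(lines, "@")]
  expect_equal(length(body), 2L)
  fields <- strsplit(body, "\t")
  expect_true(all(lengths(fields) == 11L))
  flags <- as.integer(vapply(fields, `[[`, "", 2))
  expect_equal(bitwAnd(flags, 1L), c(1L, 1L))           # paired
  expect_equal(bitwAnd(flags, 16L) > 0, c(FALSE, TRUE)) # strand bits
  expect_equal(vapply(fields, `[[`, "", 1), c("p1", "p1"))
})
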