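# Independent oracles, deliberately written as plain, slow R so they share
# no code path with the package internals they check.

# Ends-free overlap alignment identity: full DP with traceback, match +1,
# mismatch/gap -1, free terminal gaps; identity = matches / path columns.
oracle_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  S <- matrix(0, n + 1, m + 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      S[i, j] <- max(S[i - 1, j - 1] + ifelse(av[i - 1] == bv[j - 1], 1, -1),
                     S[i - 1, j] - 1, S[i, j - 1] - 1)
    }
  }
  ends <- rbind(cbind(n + 1, 1:(m + 1)), cbind(1:(n + 1), m + 1))
  best <- ends[which.max(S[ends]), ]
  i <- best[1]; j <- best[2]
  matches <- 0; cols <- 0
  while (i > 1 && j > 1) {
    diag <- S[i - 1, j - 1] + ifelse(av[i - 1] == bv[j - 1], 1, -1)
    if (S[i, j] == diag) {
      matches <- matches + (av[i - 1] == bv[j - 1]); cols <- cols + 1
      i <- i - 1; j <- j - 1
    } else if (S[i, j] == S[i - 1, j] - 1) {
      cols <- cols + 1; i <- i - 1
    } else {
      cols <- cols + 1; j <- j - 1
    }
  }
  if (cols == 0) 0 else matches / cols
}

# Trimmomatic-style trimming: LEADING, TRAILING, then 5'->3' sliding window.
oracle_quality_trim <- function(qual, window = 4, min_q = 30, lead_q = 30,
                                trail_q = 30) {
  q <- utf8ToInt(qual) - 33L
  s <- 1L
  e <- length(q)
  while (s <= e && q[s] < lead_q) s <- s + 1L
  while (e >= s && q[e] < trail_q) e <- e - 1L
  if (s <= e) {
    w <- s
    while (w + window - 1L <= e) {
      if (mean(q[w:(w + window - 1L)]) < min_q) { e <- w - 1L; break }
      w <- w + 1L
    }
  }
  if (e < s) c(0L, 0L) else c(s, e)
}

# Depth-based genotyping rule table, transcribed directly from the rules:
# heterozygote needs >= 3 of each allele and minor/major ratio > 0.1;
# homozygote needs depth >= 11 with zero reads of the other allele, or
# >= 48 with exactly one; otherwise missing.
oracle_call <- function(p, s, het_each = 3, ratio = 0.1, h0 = 11, h1 = 48) {
  if (p >= het_each && s >= het_each && min(p, s) / max(p, s) > ratio) return("het")
  if (s == 0 && p >= h0) return("hom_primary")
  if (s == 1 && p >= h1) return("hom_primary")
  if (p == 0 && s >= h0) return("hom_secondary")
  if (p == 1 && s >= h1) return("hom_secondary")
  "missing"
}

# Brute-force read mapping: mismatch count at every reference offset on
# both strands, full scan.
oracle_map <- function(read, refs, max_edit_frac = 0.07) {
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  rl <- nchar(read)
  maxmm <- floor(max_edit_frac * rl)
  hits <- list()
  for (ri in seq_along(refs)) {
    for (strand in c("+", "-")) {
      q <- if (strand == "+") read else rc(read)
      for (off in seq_len(max(0L, nchar(refs[ri]) - rl + 1L))) {
        mm <- sum(strsplit(q, "")[[1]] !=
                    strsplit(substr(refs[ri], off, off + rl - 1L), "")[[1]])
        if (mm <= maxmm) hits[[length(hits) + 1]] <-
            list(ref = ri, pos = off, strand = strand, mm = mm)
      }
    }
  }
  if (!length(hits)) return(NULL)
  mms <- vapply(hits, `[[`, numeric(1), "mm")
  best <- hits[mms == min(mms)]
  list(best = best[[1]], n_best = length(best))
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, positions) {
  for (p in positions) {
    substr(seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(seq, p, p)), 1)
  }
  seq
}
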