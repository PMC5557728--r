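make_pairs <- function(n, L = 30, seed = 1) {
  tibble::tibble(
    id = sprintf("p%05d", seq_len(n)),
    mate1 = random_dna(n, L, seed = seed),
    qual1 = strrep("F", L),
    mate2 = random_dna(n, L, seed = seed + 1),
    qual2 = strrep("F", L)
  )
}

test_that("subsampling keeps everything, nothing, or a uniform sample", {
  p <- make_pairs(100)
  expect_identical(subsample_pairs(p, 100, seed = 1), p)
  expect_identical(subsample_pairs(p, 150, seed = 1), p)
  expect_equal(nrow(subsample_pairs(p, 0, seed = 1)), 0)
  expect_error(subsample_pairs(p, -1), class = "satlib_param_error")
  expect_identical(subsample_pairs(p, 10, seed = 3),
                   subsample_pairs(p, 10, seed = 3))
})

test_that("subsampling inclusion frequencies are uniform across seeds", {
  n <- 10000
  p <- tibble::tibble(id = seq_len(n))
  inc <- numeric(n)
  n_rep <- 200
  for (s in seq_len(n_rep)) {
    keep <- subsample_pairs(p, 1000, seed = s)$id
    inc[keep] <- inc[keep] + 1
  }
  freq <- inc / n_rep
  expect_equal(mean(freq), 0.1)
  se <- sqrt(0.1 * 0.9 / n_rep)
  # ~0.3% of pairs are expected outside 3 SE by chance alone
  expect_gt(mean(abs(freq - 0.1) <= 3 * se), 0.99)
})

test_that("merging finds the documented best overlap", {
  m <- merge_pair("AAAACCCC", "CCCCGGGG", min_overlap = 4, max_mismatch_frac = 0)
  expect_true(m$merged)
  expect_equal(m$sequence, "AAAACCCCGGGG")
  expect_equal(m$overlap, 4)
  expect_equal(m$mismatches, 0)
  o <- oracle_merge("AAAACCCC", "CCCCGGGG", 4, 0)
  expect_equal(m$overlap, o$o)
  expect_equal(m$mismatches, o$mm)

  # complete overlap: mate2 is the exact reverse complement of mate1
  s <- random_dna(1, 40, seed = 2)
  full <- merge_pair(s, revcomp(s), min_overlap = 4, max_mismatch_frac = 0)
  expect_true(full$merged)
  expect_equal(full$sequence, s)
  expect_equal(full$overlap, 40)

  # disjoint sequences cannot merge
  none <- merge_pair("AAAAAAAA", "GGGGGGGG", min_overlap = 4,
                     max_mismatch_frac = 0)
  expect_false(none$merged)
  expect_true(is.na(none$sequence))

  expect_error(merge_pair("", "ACGT"), class = "satlib_param_error")
  expect_error(merge_pair("ACGT", "ACGT", min_overlap = 0),
               class = "satlib_param_error")
})

test_that("merge agrees with the overlap-enumeration oracle on random pairs", {
  withr::with_seed(11, {
    for (i in 1:25) {
      L <- sample(40:55, 1)
      frag <- random_dna(1, sample((L + 5):(2 * L - 12), 1))
      m1 <- substr(frag, 1, L)
      m2 <- revcomp(substr(frag, nchar(frag) - L + 1, nchar(frag)))
      got <- merge_pair(m1, m2, min_overlap = 10, max_mismatch_frac = 0.1)
      want <- oracle_merge(m1, m2, 10, 0.1)
      expect_true(got$merged)
      expect_equal(got$overlap, want$o)
      expect_equal(got$sequence, frag)
    }
  })
})

test_that("merging is symmetric under mate swap with reverse complement", {
  withr::with_seed(12, {
    for (i in 1:20) {
      frag <- random_dna(1, 70)
      m1 <- substr(frag, 1, 45)
      m2 <- revcomp(substr(frag, 26, 70))
      a <- merge_pair(m1, m2, min_overlap = 10, max_mismatch_frac = 0.1)
      b <- merge_pair(m2, m1, min_overlap = 10, max_mismatch_frac = 0.1)
      expect_true(a$merged && b$merged)
      expect_equal(a$sequence, revcomp(b$sequence))
    }
  })
})

test_that("overlap mismatches resolve to the higher-quality base", {
  frag <- random_dna(1, 60, seed = 4)
  m1 <- substr(frag, 1, 40)
  m2raw <- substr(frag, 21, 60)
  # corrupt one overlap base on mate 1
  s <- strsplit(m1, "")[[1]]
  s[30] <- setdiff(c("A", "C", "G", "T"), s[30])[1]
  m1c <- paste(s, collapse = "")
  hiq <- strrep("I", 40); loq <- strrep("#", 40)
  m <- merge_pair(m1c, revcomp(m2raw), qual1 = loq, qual2 = hiq,
                  min_overlap = 10, max_mismatch_frac = 0.2)
  expect_equal(m$sequence, frag)  # mate 2 base wins
  m2 <- merge_pair(m1c, revcomp(m2raw), qual1 = hiq, qual2 = loq,
                   min_overlap = 10, max_mismatch_frac = 0.2)
  expect_equal(substr(m2$sequence, 30, 30), s[30])  # mate 1 base wins
  # quality tie resolves to mate 1
  m3 <- merge_pair(m1c, revcomp(m2raw), qual1 = hiq, qual2 = hiq,
                   min_overlap = 10, max_mismatch_frac = 0.2)
  expect_equal(substr(m3$sequence, 30, 30), s[30])
})

test_that("merged error-free reads are substrings of the circular array", {
  arr <- build_tandem_array(random_dna(15, 90, seed = 8), seed = 8)
  reads <- generate_reads(arr, 100, read_length = 101, frag_mean = 150,
                          frag_sd = 8, error_rate = 0, seed = 9)
  merged <- merge_pairs(reads, min_overlap = 20, max_mismatch_frac = 0)
  expect_true(all(merged$merged))
  doubled <- paste0(arr$sequence, arr$sequence)
  expect_true(all(vapply(merged$sequence, grepl, logical(1), x = doubled,
                         fixed = TRUE)))
})

test_that("homology selection finds consensus substrings on both strands", {
  cons <- sat_consensus("TestSat01-177", random_dna(1, 177, seed = 21))
  sub <- substr(cons$sequence, 30, 89)
  hits <- select_homologous(c(sub, revcomp(sub)), cons,
                            min_identity = 0.70, min_aligned = 50)
  expect_true(all(hits$hit))
  expect_equal(hits$identity, c(1, 1))
  expect_equal(hits$strand, c("+", "-"))

  # straddles the consensus start: needs the doubled reference
  straddle <- paste0(substr(cons$sequence, 150, 177), substr(cons$sequence, 1, 40))
  h2 <- select_homologous(straddle, cons)
  expect_true(h2$hit)
  expect_equal(h2$identity, 1)
})

test_that("random queries are rejected at the default thresholds", {
  cons <- random_dna(1, 177, seed = 22)
  qs <- random_dna(25, 100, seed = 23)
  hits <- select_homologous(qs, cons, min_identity = 0.70, min_aligned = 50)
  expect_false(any(hits$hit))
})

test_that("alignment scores match an affine-gap DP oracle", {
  withr::with_seed(31, {
    for (i in 1:6) {
      q <- random_dna(1, 40)
      s <- random_dna(1, 90)
      expect_equal(satlib:::align_many(q, s, type = "local")$score,
                   oracle_score(q, s, type = "local"))
      expect_equal(satlib:::align_many(q, s, type = "global")$score,
                   oracle_score(q, s, type = "global"))
    }
    # and on homologous pairs with a planted indel
    base <- random_dna(1, 60)
    mut <- paste0(substr(base, 1, 20), substr(base, 25, 60))
    expect_equal(satlib:::align_many(mut, base, type = "global")$score,
                 oracle_score(mut, base, type = "global"))
  })
})

test_that("queries shorter than min_aligned warn and N-heavy queries drop", {
  cons <- random_dna(1, 177, seed = 24)
  expect_warning(
    h <- select_homologous(c(substr(cons, 1, 20)), cons, min_aligned = 50),
    "skipped"
  )
  expect_false(h$hit[1])
  nq <- paste0(strrep("N", 30), substr(cons, 1, 70))
  h2 <- select_homologous(nq, cons)  # 30% N -> dropped
  expect_false(h2$hit)
  expect_error(select_homologous("ACGT", ""), class = "satlib_param_error")
})
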