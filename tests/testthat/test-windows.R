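test_that("p-distance obeys identity, symmetry and pairwise deletion", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("AAAAAAAAAA", "AAAATAAAAA"), 0.10)
  expect_equal(p_distance("AC-T", "ACGT"), 0)          # gap column dropped
  expect_equal(p_distance("ACNT", "ACGA"), 1 / 3)      # N column dropped
  a <- random_seq(300, seed = 1); b <- random_seq(300, seed = 2)
  expect_equal(p_distance(a, b), p_distance(b, a))
  expect_true(is.na(p_distance("---", "AAA")))
})

test_that("sliding profile equals brute-force recomputation on a toy", {
  set.seed(31)
  aln <- matrix(sample(c("A", "C", "G", "T", "-"), 4 * 40, replace = TRUE,
                       prob = c(rep(0.23, 4), 0.08)), nrow = 4)
  w <- 5L
  prof <- sliding_pdistance_profile(aln, w, step = 1, circular = TRUE)
  ext <- cbind(aln, aln[, 1:(w - 1)])
  for (s in prof$start) {
    cols <- (s + 1):(s + w)
    brute <- 0
    for (i in 1:3) for (j in (i + 1):4) {
      d <- p_distance(ext[i, cols], ext[j, cols])
      if (!is.na(d)) brute <- max(brute, d)
    }
    expect_equal(prof$max_p_distance[prof$start == s], brute)
  }
})

test_that("profile of identical rows is identically zero", {
  aln <- rbind(a = strsplit(random_seq(100, seed = 3), "")[[1]],
               b = strsplit(random_seq(100, seed = 3), "")[[1]])
  prof <- sliding_pdistance_profile(aln, 10)
  expect_true(all(prof$max_p_distance == 0))
})

test_that("rotating a circular alignment rotates, not changes, the profile", {
  set.seed(41)
  aln <- matrix(sample(c("A", "C", "G", "T"), 3 * 60, replace = TRUE), 3)
  prof <- sliding_pdistance_profile(aln, 8)$max_p_distance
  k <- 17
  rot <- aln[, c((k + 1):60, 1:k)]
  prof_rot <- sliding_pdistance_profile(rot, 8)$max_p_distance
  expect_equal(prof_rot, prof[c((k + 1):60, 1:k)])
})

test_that("partitioning splits a step-function profile at the change point", {
  prof <- c(rep(0.05, 50), rep(0.30, 50))
  w <- partition_by_divergence(prof, min_block = 10, min_overlap = 5,
                               circular = FALSE, aln_length = 100)
  expect_equal(nrow(w), 2)
  expect_lte(abs(w$start[2] - 50), 1)
  v <- validate_windows(w, 5, 100)
  expect_true(v$covers_alignment)
  expect_equal(v$min_consecutive_overlap, 5)
})

test_that("a flat profile yields one whole-circle window", {
  w <- partition_by_divergence(rep(0.2, 200), min_block = 20,
                               min_overlap = 50, circular = TRUE,
                               aln_length = 200)
  expect_equal(nrow(w), 1)
  v <- validate_windows(w, 50, 200)
  expect_true(v$covers_alignment)
  expect_true(is.na(v$min_consecutive_overlap))
})

test_that("circular partitions of a divergence-structured alignment pass
           validation", {
  set.seed(51)
  vals <- rep(c(0.05, 0.22, 0.12, 0.30), each = 250) +
    runif(1000, 0, 0.02)
  w <- partition_by_divergence(vals, min_block = 100, min_overlap = 50,
                               circular = TRUE, aln_length = 1000)
  v <- validate_windows(w, 50, 1000)
  expect_true(v$covers_alignment)
  expect_gte(v$min_consecutive_overlap, 50)
})

test_that("window overlap arithmetic matches simple cases", {
  w <- data.frame(start = c(0, 90), end = c(100, 200))
  v <- validate_windows(w, 10, 200)
  expect_equal(v$min_consecutive_overlap, 10)
  ## wrapped final window
  w2 <- data.frame(start = c(0, 150), end = c(160, 10))
  v2 <- validate_windows(w2, 10, 200)
  expect_equal(v2$overlaps, c(10, 10))
  expect_true(v2$covers_alignment)
})

test_that("window consensus matches an independent per-column tally", {
  aln <- rbind(strsplit("ACGTAC", "")[[1]],
               strsplit("ACGTTC", "")[[1]],
               strsplit("ATGT-C", "")[[1]],
               strsplit("ATGTTC", "")[[1]])
  cons <- window_consensus(aln, 0, 6)
  ## col2 tie A/T -> W; col5 majority T (gap is minority)
  expect_identical(cons, "AYGTTC")
  ## tie case from two-base columns
  aln2 <- rbind(c("A"), c("A"), c("T"), c("T"))
  expect_identical(window_consensus(aln2, 0, 1), "W")
  ## majority-gap column dropped
  aln3 <- rbind(strsplit("A-C", "")[[1]], strsplit("A-C", "")[[1]],
                strsplit("AGC", "")[[1]])
  expect_identical(window_consensus(aln3, 0, 3), "AC")
  ## row order invariance
  set.seed(61)
  m <- matrix(sample(c("A", "C", "G", "T", "-"), 5 * 30, replace = TRUE), 5)
  expect_identical(window_consensus(m, 0, 30),
                   window_consensus(m[sample(5), ], 0, 30))
})

test_that("consensus of identical rows equals the row with gaps removed", {
  row <- "AC-GT-ACA"
  aln <- rbind(strsplit(row, "")[[1]], strsplit(row, "")[[1]],
               strsplit(row, "")[[1]])
  expect_identical(window_consensus(aln, 0, 9), gsub("-", "", row))
})

test_that("extraction thresholds follow the additive rule with a cap", {
  expect_equal(compute_threshold(0.22, 0.10), 0.32)
  expect_equal(compute_threshold(0.35, 0.10), 0.45)
  expect_equal(compute_threshold(0.95, 0.10), 1.0)
  expect_equal(compute_threshold(0.22, 0.10, mode = "multiplicative"),
               0.242)
})

test_that("the printed 16-window reduction table satisfies its own rules", {
  w <- windows_fixture()
  v <- validate_windows(w, 50, 16440)
  expect_equal(v$min_consecutive_overlap, 50)
  expect_true(v$covers_alignment)
  ## the divergence column spans the 18-35% range
  expect_equal(range(w$max_divergence_pct), c(18, 35))
  ## additive thresholds stay below 0.5
  expect_true(all(compute_threshold(w$max_divergence_pct / 100, 0.10) <=
                    0.45))
})
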