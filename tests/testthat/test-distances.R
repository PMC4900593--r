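test_that("LogDet is zero on identity, symmetric, and NA when singular", {
  s <- random_seq(500, seed = 111, freqs = c(0.4, 0.1, 0.1, 0.4))
  expect_equal(logdet_distance(s, s), 0)
  a <- random_seq(400, seed = 112)
  b <- random_seq(400, seed = 113)
  expect_equal(logdet_distance(a, b), logdet_distance(b, a))
  ## a base absent from one sequence -> singular joint matrix
  no_t <- gsub("T", "A", a)
  d <- logdet_distance(no_t, b)
  expect_true(is.na(d))
  expect_match(attr(d, "reason"), "singular")
})

test_that("LogDet agrees with the JC correction under stationary JC", {
  g <- genome_pair(30000, 0.2, seed = 114)
  x <- g$alignment["X", ]; y <- g$alignment["Y", ]
  ld <- logdet_distance(x, y)
  p <- p_distance(x, y)
  jc <- -0.75 * log(1 - 4 / 3 * p)
  expect_equal(ld, jc, tolerance = 0.02)
  ## and with ape's independent JC69 implementation
  db <- ape::dist.dna(ape::as.DNAbin(g$alignment), model = "JC69")
  expect_equal(ld, as.numeric(db), tolerance = 0.02)
})

test_that("LogDet recovers additive truth under compositional drift where
           the JC correction is biased", {
  ## truth from the closed-form expected joint distribution of the
  ## non-stationary process (independent oracle)
  f81P <- function(t, pi) {
    mu <- 1 / (1 - sum(pi^2))
    e <- exp(-mu * t)
    P <- (1 - e) * matrix(rep(pi, each = 4), 4, 4)
    diag(P) <- diag(P) + e
    P
  }
  paralinear <- function(F) {
    -0.25 * (log(det(F)) -
               0.5 * (sum(log(rowSums(F))) + sum(log(colSums(F)))))
  }
  piX <- c(0.42, 0.08, 0.08, 0.42)
  piY <- c(0.08, 0.42, 0.42, 0.08)
  t_branch <- 0.15
  Px <- f81P(t_branch, piX); Py <- f81P(t_branch, piY)
  F_true <- t(Px) %*% diag(rep(0.25, 4)) %*% Py
  d_true <- paralinear(F_true)

  mod <- substitution_model("f81",
                            lineage_freqs = list(X = piX, Y = piY))
  n_rep <- 40; n_sites <- 10000
  est <- jc <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    g <- simulate_genomes(
      evolution_spec(sprintf("(X:%f,Y:%f);", t_branch, t_branch), mod,
                     seed = 7000 + r), n_sites)
    est[r] <- logdet_distance(g$alignment["X", ], g$alignment["Y", ])
    p <- p_distance(g$alignment["X", ], g$alignment["Y", ])
    jc[r] <- -0.75 * log(1 - 4 / 3 * p)
  }
  sd_est <- sd(est)
  expect_lt(abs(est[1] - d_true), 3 * sd_est)
  expect_lt(abs(mean(est) - d_true), 3 * sd_est / sqrt(n_rep))
  ## the stationarity-assuming correction misses the additive truth
  expect_gt(abs(mean(jc) - d_true), abs(mean(est) - d_true))
})

test_that("composition test matches the direct chi-square formula", {
  ## identical compositions -> statistic 0, p 1
  aln <- rbind(a = rep(c("A", "C", "G", "T"), 25),
               b = rep(c("A", "C", "G", "T"), 25))
  ct <- composition_chi2(aln)
  expect_equal(ct$statistic, 0)
  expect_equal(ct$p_value, 1)
  ## 2-taxon toy with counts {{40,10,10,40},{10,40,40,10}}:
  ## all E = 25, statistic = 8 * 15^2 / 25 = 72
  t1 <- c(rep("A", 40), rep("C", 10), rep("G", 10), rep("T", 40))
  t2 <- c(rep("A", 10), rep("C", 40), rep("G", 40), rep("T", 10))
  ct2 <- composition_chi2(rbind(a = t1, b = t2))
  expect_equal(ct2$statistic, 72)
  expect_equal(ct2$df, 3)
  expect_equal(ct2$statistic,
               unname(stats::chisq.test(ct2$table, correct = FALSE)
                      $statistic))
  ## df for 7 taxa, 4 bases
  set.seed(115)
  aln7 <- matrix(sample(c("A", "C", "G", "T"), 7 * 200, replace = TRUE), 7)
  expect_equal(composition_chi2(aln7)$df, 18)
})

test_that("NJ reproduces additive matrices exactly", {
  tr <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:4):1);")
  dm <- cophenetic(tr)
  nj <- nj_me_tree(dm)
  expect_equal(cophenetic(nj)[rownames(dm), colnames(dm)], dm,
               tolerance = 1e-10)
  expect_equal(ape::dist.topo(ape::unroot(tr), nj), 0,
               ignore_attr = TRUE)
  ## 3 taxa: closed-form three-point branch lengths
  d3 <- matrix(c(0, 5, 6, 5, 0, 7, 6, 7, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_me_tree(d3)
  expect_setequal(round(t3$edge.length, 10), c(2, 3, 4))
  ## undefined entries rejected with the offending pair named
  dna <- dm; dna["a", "c"] <- dna["c", "a"] <- NA
  expect_error(nj_me_tree(dna), "a-c")
})

test_that("bootstrap recovers a clean split in essentially all replicates", {
  ## two 3-taxon clusters, shallow within and deep between
  tr <- "(((A:0.02,B:0.02):0.02,C:0.04):0.08,((D:0.02,E:0.02):0.02,F:0.04):0.08);"
  g <- simulate_genomes(evolution_spec(tr, seed = 116), 5000)
  bs <- bootstrap_trees(g$alignment, n_reps = 100, method = "logdet",
                        seed = 5)
  expect_equal(bs$n, 100)
  ## count the ABC | DEF split via rooted support after outgroup-free
  ## rooting on the split itself
  n_split <- sum(vapply(bs$trees, function(t) {
    parts <- ape::prop.part(ape::root(t, outgroup = "F",
                                      resolve.root = TRUE))
    any(vapply(parts, function(p)
      setequal(attr(parts, "labels")[p], c("A", "B", "C")), logical(1)))
  }, logical(1)))
  expect_gte(n_split / 100, 0.99)
})

test_that("bootstrap is reproducible and invariant to column order", {
  g <- simulate_genomes(
    evolution_spec("((A:0.05,B:0.05):0.05,(C:0.05,D:0.05):0.05);",
                   seed = 117), 1500)
  b1 <- bootstrap_trees(g$alignment, 25, seed = 9)
  b2 <- bootstrap_trees(g$alignment, 25, seed = 9)
  expect_identical(lapply(b1$trees, ape::write.tree),
                   lapply(b2$trees, ape::write.tree))
  ## column order: support for the AB split is unchanged under permutation
  count_ab <- function(sample) sum(vapply(sample$trees, function(t) {
    parts <- ape::prop.part(ape::root(t, "D", resolve.root = TRUE))
    any(vapply(parts, function(p)
      setequal(attr(parts, "labels")[p], c("A", "B")), logical(1)))
  }, logical(1)))
  set.seed(10)
  perm <- sample(ncol(g$alignment))
  b3 <- bootstrap_trees(g$alignment[, perm], 25, seed = 9)
  expect_lte(abs(count_ab(b3) - count_ab(b1)), 3)
})
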