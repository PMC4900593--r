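test_that("clade and rooted-topology counts match their closed forms", {
  expect_equal(length(enumerate_clades(4)), 10)
  expect_equal(length(enumerate_clades(3)), 3)
  expect_equal(length(enumerate_clades(5)), 25)
  dfact <- function(n) prod(seq(2 * n - 3, 1, by = -2))
  for (n in 2:7)
    expect_equal(length(enumerate_rooted_trees(n)), dfact(n))
  expect_equal(length(enumerate_rooted_trees(4)), 15)
  expect_error(enumerate_rooted_trees(10), "n > 9")
  ## canonical forms are pairwise distinct and stable under re-parsing
  keys <- enumerate_rooted_trees(4)
  expect_equal(anyDuplicated(keys), 0)
  reparsed <- vapply(keys, function(k)
    topology_key(ape::read.tree(text = paste0(k, ";"))), character(1))
  expect_identical(unname(reparsed), keys)
})

test_that("enumeration agrees with an independent stepwise oracle", {
  skip_if_not_installed("phangorn")
  mine <- enumerate_rooted_trees(5)
  oracle <- phangorn::allTrees(5, rooted = TRUE,
                               tip.label = LETTERS[1:5])
  okeys <- sort(vapply(oracle, topology_key, character(1)))
  expect_identical(mine, okeys)
})

test_that("a degenerate sample puts its clades at 100% and others at 0", {
  ts <- simulate_treeset(c("A", "B", "L", "R"), 200,
                         topology_probs = c("((A,B),(L,R));" = 1), seed = 1)
  s <- full_split_support(ts)
  hit <- s$clades$percent[s$clades$clade %in% c("A,B", "L,R")]
  expect_equal(hit, c(100, 100))
  expect_equal(sum(s$clades$percent > 0), 2)
  expect_equal(sum(s$topologies$percent), 100)
  expect_equal(max(s$topologies$percent), 100)
})

test_that("uniform sampling over the 15 topologies is multinomially fair", {
  n <- 15000
  probs <- stats::setNames(rep(1 / 15, 15),
                           paste0(enumerate_rooted_trees(4), ";"))
  ts <- simulate_treeset(4, n, topology_probs = probs, seed = 2)
  s <- full_split_support(ts)
  se <- sqrt((1 / 15) * (14 / 15) / n)
  expect_true(all(abs(s$topologies$percent / 100 - 1 / 15) <= 3 * se))
  ## consistency identity: clade support = sum of supporting topologies
  topo_keys <- s$topologies$topology
  topo_clades <- lapply(topo_keys, function(k)
    mitopool:::tree_clade_keys(ape::read.tree(text = paste0(k, ";"))))
  for (i in seq_len(nrow(s$clades))) {
    ck <- mitopool:::clade_key(strsplit(s$clades$clade[i], ",")[[1]])
    contains <- vapply(topo_clades, function(x) ck %in% x, logical(1))
    expect_equal(s$clades$percent[i],
                 sum(s$topologies$percent[contains]), tolerance = 1e-9)
  }
})

test_that("a two-topology mixture reports shared and private clades", {
  ts <- simulate_treeset(4, 10000,
                         topology_probs = c("((A,B),(C,D));" = 0.6,
                                            "(((A,B),C),D);" = 0.4),
                         seed = 3)
  s <- full_split_support(ts)
  pc <- stats::setNames(s$clades$percent, s$clades$clade)
  expect_equal(unname(pc["A,B"]), 100)
  se3 <- 3 * sqrt(0.6 * 0.4 / 10000) * 100
  expect_lt(abs(pc["C,D"] - 60), se3)
  expect_lt(abs(pc["A,B,C"] - 40), se3)
})

test_that("clade targets are solved for, or rejected when unrealisable", {
  ts <- simulate_treeset(4, 8000,
                         clade_targets = c("A,B" = 0.7, "C,D" = 0.7),
                         seed = 4)
  s <- full_split_support(ts)
  pc <- stats::setNames(s$clades$percent, s$clades$clade)
  expect_lt(abs(pc["A,B"] - 70), 3 * sqrt(0.7 * 0.3 / 8000) * 100)
  ## disjoint pairs cannot both be clades 100% of the time with A,C at 50%
  expect_error(
    simulate_treeset(4, 10,
                     clade_targets = c("A,B" = 1, "A,C" = 0.5)),
    "no distribution")
})

test_that("partial-split support follows the worked pruning examples", {
  t_sup <- ape::read.tree(text = "((A,B),(L,R));")
  t_not <- ape::read.tree(text = "((A,L),(B,R));")
  expect_equal(partial_split_support(tree_sample(t_sup),
                                     c("A", "B"))$percent, 100)
  expect_equal(partial_split_support(tree_sample(t_not),
                                     c("A", "B"))$percent, 0)
  ## ((A,(B,L)),R) pruned to {A,B,L} displays (B,L), not (A,B)
  t3 <- ape::read.tree(text = "((A,(B,L)),R);")
  expect_equal(partial_split_support(tree_sample(t3), c("A", "B"),
                                     c("A", "B", "L"))$percent, 0)
  expect_equal(partial_split_support(tree_sample(t3), c("B", "L"),
                                     c("A", "B", "L"))$percent, 100)
  ## trivial induced problems are flagged uninformative
  r <- partial_split_support(tree_sample(t3), c("A", "B"), c("A", "B"))
  expect_false(r$informative)
})

test_that("full and partial support match a brute-force prune-and-check
           oracle on random 6-leaf samples", {
  skip_if_not_installed("phangorn")
  set.seed(5)
  leaves <- LETTERS[1:6]
  trees <- replicate(30, ape::rtree(6, tip.label = sample(leaves)),
                     simplify = FALSE)
  samp <- tree_sample(trees, "random")
  ## oracle: clade present iff the MRCA's descendant tips equal the clade
  oracle_has <- function(tree, clade) {
    m <- ape::getMRCA(tree, clade)
    tips <- tree$tip.label[phangorn::Descendants(tree, m, "tips")[[1]]]
    setequal(tips, clade)
  }
  queries <- list(
    list(clade = c("A", "B"), taxa = leaves),
    list(clade = c("C", "D", "E"), taxa = leaves),
    list(clade = c("A", "B"), taxa = c("A", "B", "C")),
    list(clade = c("B", "E"), taxa = c("A", "B", "E", "F")),
    list(clade = c("A", "C", "F"), taxa = c("A", "B", "C", "F")))
  for (q in queries) {
    got <- partial_split_support(samp, q$clade, q$taxa)$percent
    want <- 100 * mean(vapply(trees, function(t) {
      pt <- if (length(q$taxa) < 6) ape::keep.tip(t, q$taxa) else t
      oracle_has(pt, q$clade)
    }, logical(1)))
    expect_equal(got, want)
  }
  ## pruning can only preserve or create displays, never destroy them
  full <- partial_split_support(samp, c("A", "B"), leaves)$percent
  part <- partial_split_support(samp, c("A", "B"), c("A", "B", "C",
                                                     "D"))$percent
  expect_gte(part, full)
})

test_that("support is invariant under consistent relabelling", {
  ts <- simulate_treeset(4, 500,
                         topology_probs = c("((A,B),(C,D));" = 0.5,
                                            "(((A,C),B),D);" = 0.5),
                         seed = 6)
  relab <- c(A = "W", B = "X", C = "Y", D = "Z")
  trees2 <- lapply(ts$trees, function(t) {
    t$tip.label <- unname(relab[t$tip.label]); t
  })
  s1 <- full_split_support(ts)
  s2 <- full_split_support(tree_sample(trees2, "relabelled"))
  key1 <- vapply(strsplit(s1$clades$clade, ","), function(x)
    paste(sort(unname(relab[x])), collapse = ","), character(1))
  expect_equal(stats::setNames(s1$clades$percent, key1)[s2$clades$clade],
               stats::setNames(s2$clades$percent, s2$clades$clade))
})

test_that("taxon reduction collapses proven clades and enforces tolerance", {
  good <- ape::read.tree(text = "(((GL,GS),(GA,HB)),PC);")
  bad <- ape::read.tree(text = "(((GL,HB),(GA,GS)),PC);")
  samp <- tree_sample(c(replicate(18, good, simplify = FALSE),
                        replicate(2, bad, simplify = FALSE)), "BI")
  expect_error(reduce_taxa(samp, list(L = c("GL", "GS")), "PC"),
               "non-monophyletic in 2/20")
  red <- reduce_taxa(samp, list(L = c("GL", "GS")), "PC", tol = 0.15)
  expect_setequal(red$leaves, c("GA", "HB", "L"))
  ## after reduction the problem has the expected combinatorics
  expect_equal(length(enumerate_clades(red$leaves)), 3)
  ## identity collapse only reroots and drops the outgroup
  red2 <- reduce_taxa(tree_sample(replicate(5, good, simplify = FALSE)),
                      collapse = list(), root_taxon = "PC")
  expect_setequal(red2$leaves, c("GA", "GL", "GS", "HB"))
})

test_that("the analyses x clades table renders zeros as dashes", {
  s1 <- simulate_treeset(4, 400,
                         topology_probs = c("((A,B),(C,D));" = 1), seed = 7)
  s2 <- simulate_treeset(4, 400,
                         topology_probs = c("((A,B),(C,D));" = 0.5,
                                            "(((A,B),C),D);" = 0.5),
                         seed = 8)
  tab <- support_table(list(`deg` = s1, `mix` = s2))
  expect_equal(ncol(tab), 10)
  expect_identical(tab["deg", "AB"], "100.0")
  expect_identical(tab["deg", "AC"], "-")
  pct <- attr(tab, "percent")
  expect_equal(pct["deg", "AB"], 100)
  expect_lt(abs(pct["mix", "CD"] - 50), 8)
})
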