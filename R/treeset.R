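#' Tree sample
#'
#' A collection of trees on a shared leaf set, e.g. a posterior sample or a
#' set of bootstrap trees, labelled by the analysis that produced it.
#'
#' @param trees a \code{multiPhylo}, list of \code{phylo}, or single
#'   \code{phylo}.
#' @param source analysis label (e.g. \code{"BI All"}, \code{"LD PC"}).
#' @export
tree_sample <- function(trees, source = "sample") {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(trees, function(t) {
    if (!inherits(t, "phylo")) stop("trees must be phylo objects")
    t
  })
  class(trees) <- "multiPhylo"
  leaf_sets <- lapply(trees, function(t) sort(t$tip.label))
  if (length(unique(vapply(leaf_sets, paste, character(1),
                           collapse = "\r"))) != 1L)
    stop("all trees must share the same leaf set")
  structure(list(trees = trees, n = length(trees), source = source,
                 leaves = leaf_sets[[1]]),
            class = "tree_sample")
}

#' @export
print.tree_sample <- function(x, ...) {
  cat(sprintf("<tree_sample> '%s': %d trees on %d leaves (%s)\n",
              x$source, x$n, length(x$leaves),
              paste(x$leaves, collapse = ", ")))
  invisible(x)
}

#' Subsample a tree sample uniformly
#' @param sample a [tree_sample()].
#' @param m number of trees to draw (with replacement if m > n).
#' @param seed RNG seed.
#' @export
subsample_trees <- function(sample, m, seed = NULL) {
  with_seed(seed, {
    idx <- sample.int(sample$n, m, replace = m > sample$n)
    tree_sample(sample$trees[idx], sample$source)
  })
}

## ---- rooted-tree machinery ------------------------------------------------

## Children of every node, as a list indexed by node number.
phylo_children <- function(tree) {
  kids <- vector("list", max(tree$edge))
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1]]] <- c(kids[[tree$edge[e, 1]]], tree$edge[e, 2])
  kids
}

## Canonical clade key: taxa sorted and joined.
clade_key <- function(taxa) paste(sort(taxa), collapse = "|")

## All nontrivial clades (as keys) of a rooted tree.
tree_clade_keys <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- phylo_children(tree)
  tipsets <- vector("list", max(tree$edge))
  keys <- character(0)
  walk <- function(v) {
    if (v <= ntip) {
      tipsets[[v]] <<- tree$tip.label[v]
      return(tipsets[[v]])
    }
    s <- sort(unlist(lapply(kids[[v]], walk)))
    tipsets[[v]] <<- s
    if (length(s) >= 2L && length(s) < ntip)
      keys <<- c(keys, clade_key(s))
    s
  }
  walk(ntip + 1L)
  keys
}

#' Canonical form of a rooted topology
#'
#' A sorted-newick string with lexicographically ordered children; two
#' rooted trees have the same key iff they have the same topology
#' (branch lengths ignored).
#'
#' @param tree a rooted \code{phylo}.
#' @return character scalar (newick without the trailing semicolon).
#' @export
topology_key <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- phylo_children(tree)
  key <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    paste0("(", paste(sort(vapply(kids[[v]], key, character(1))),
                      collapse = ","), ")")
  }
  key(ntip + 1L)
}

#' Enumerate all possible clades on a leaf set
#'
#' All subsets of size 2..n-1, i.e. every nontrivial clade a rooted tree on
#' these leaves could contain; there are \eqn{2^n - n - 2} of them (10 for
#' n = 4).
#'
#' @param leaves character vector of labels, or a single integer n (labels
#'   then taken from LETTERS).
#' @return list of character vectors (each a clade), in size-then-lexical
#'   order.
#' @export
enumerate_clades <- function(leaves) {
  if (is.numeric(leaves) && length(leaves) == 1L)
    leaves <- LETTERS[seq_len(leaves)]
  n <- length(leaves)
  if (n < 2L) stop("need >= 2 leaves")
  leaves <- sort(leaves)
  out <- list()
  for (k in 2:(n - 1)) {
    if (k > n - 1) break
    cmb <- utils::combn(leaves, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Enumerate all rooted binary labelled topologies
#'
#' Generates every rooted binary tree shape on the given leaves by stepwise
#' leaf addition (a new leaf can be attached on any of the \eqn{2m - 1}
#' edges of an m-leaf rooted tree, including above the root), yielding
#' \eqn{(2n-3)!!} distinct topologies, each returned once in canonical form.
#'
#' @param leaves labels or a single integer n (max 9; the enumeration is
#'   combinatorial).
#' @return character vector of canonical newick strings (see
#'   [topology_key()]).
#' @export
enumerate_rooted_trees <- function(leaves) {
  if (is.numeric(leaves) && length(leaves) == 1L)
    leaves <- LETTERS[seq_len(leaves)]
  n <- length(leaves)
  if (n < 2L) stop("need >= 2 leaves")
  if (n > 9L) stop("refusing to enumerate rooted topologies for n > 9")
  leaves <- sort(leaves)
  ## nested-list representation: leaf = label, node = list(left, right)
  trees <- list(list(leaves[1], leaves[2]))
  insert_everywhere <- function(tree, leaf) {
    out <- list(list(tree, leaf))             # above the current root
    if (!is.list(tree)) return(out)
    for (i in 1:2) {
      for (sub in insert_everywhere(tree[[i]], leaf)) {
        t2 <- tree
        t2[[i]] <- sub
        out <- c(out, list(t2))
      }
    }
    out
  }
  for (k in seq_len(n - 2) + 2L) {
    trees <- unlist(lapply(trees, insert_everywhere, leaf = leaves[k]),
                    recursive = FALSE)
  }
  canon <- function(t) {
    if (!is.list(t)) return(t)
    paste0("(", paste(sort(c(canon(t[[1]]), canon(t[[2]]))), collapse = ","),
           ")")
  }
  keys <- vapply(trees, canon, character(1))
  if (anyDuplicated(keys)) keys <- unique(keys)
  sort(keys)
}

## ---- taxon reduction ------------------------------------------------------

#' Reduce the taxon set of a tree sample
#'
#' Roots every tree on a designated outgroup, verifies that each collapse
#' set is monophyletic across the sample, and replaces each set by a single
#' leaf, turning a many-taxon problem into a small-taxon one (the classic
#' move that reduces a radiation with proven subclades to, say, a four-taxon
#' problem).
#'
#' @param sample a [tree_sample()].
#' @param collapse named list: new label -> character vector of taxa to
#'   collapse into one leaf. Singleton sets simply rename a taxon.
#' @param root_taxon outgroup leaf used to root every tree; once the
#'   rooting is fixed the outgroup is dropped, leaving the rooted problem
#'   on the remaining (reduced) taxa.
#' @param tol maximum tolerated fraction of trees in which a collapse set is
#'   non-monophyletic (default 0: must be a clade in every tree).
#' @param drop taxa to remove entirely (e.g. extra conspecific individuals)
#'   before collapsing.
#' @return A new [tree_sample()] on the reduced leaf set (rooted trees).
#' @export
reduce_taxa <- function(sample, collapse = list(), root_taxon,
                        tol = 0, drop = character()) {
  stopifnot(inherits(sample, "tree_sample"))
  if (!root_taxon %in% sample$leaves)
    stop("root_taxon '", root_taxon, "' not in the leaf set")
  trees <- lapply(sample$trees, function(t) {
    t <- ape::root(t, outgroup = root_taxon, resolve.root = TRUE)
    if (length(drop)) t <- ape::drop.tip(t, drop)
    t
  })
  for (lab in names(collapse)) {
    set <- collapse[[lab]]
    set <- setdiff(set, drop)
    if (length(set) < 1L) stop("collapse set '", lab, "' is empty")
    if (root_taxon %in% set)
      stop("collapse set '", lab, "' must not contain the root taxon")
    if (length(set) > 1L) {
      key <- clade_key(set)
      bad <- sum(vapply(trees, function(t) !key %in% tree_clade_keys(t),
                        logical(1)))
      if (bad > tol * length(trees))
        stop(sprintf(
          "collapse set '%s' is non-monophyletic in %d/%d trees (%.1f%%)",
          lab, bad, length(trees), 100 * bad / length(trees)))
    }
    trees <- lapply(trees, function(t) {
      if (length(set) > 1L) t <- ape::drop.tip(t, set[-1])
      t$tip.label[t$tip.label == set[1]] <- lab
      t
    })
  }
  trees <- lapply(trees, ape::drop.tip, tip = root_taxon)
  tree_sample(trees, sample$source)
}

## ---- support summaries ----------------------------------------------------

#' Frequency-of-occurrence support for all full splits and topologies
#'
#' For every possible clade on the sample's leaf set, the percentage of
#' trees containing it; and for every possible rooted binary topology, the
#' percentage of trees with exactly that topology.
#'
#' @param sample a [tree_sample()] of rooted trees.
#' @return list with \code{clades} (data.frame: clade, percent) and
#'   \code{topologies} (data.frame: topology, percent).
#' @export
full_split_support <- function(sample) {
  stopifnot(inherits(sample, "tree_sample"))
  if (!all(vapply(sample$trees, ape::is.rooted, logical(1))))
    stop("all trees must be rooted; use reduce_taxa() or ape::root() first")
  leaves <- sample$leaves
  clades <- enumerate_clades(leaves)
  keys <- vapply(clades, clade_key, character(1))
  counts <- stats::setNames(numeric(length(keys)), keys)
  topo_keys <- enumerate_rooted_trees(leaves)
  topo_counts <- stats::setNames(numeric(length(topo_keys)), topo_keys)
  for (t in sample$trees) {
    ck <- tree_clade_keys(t)
    hit <- keys %in% ck
    counts[hit] <- counts[hit] + 1
    tk <- topology_key(t)
    if (tk %in% topo_keys) topo_counts[tk] <- topo_counts[tk] + 1
  }
  list(
    clades = data.frame(
      clade = vapply(clades, function(s) paste(s, collapse = ","),
                     character(1)),
      percent = 100 * unname(counts) / sample$n,
      stringsAsFactors = FALSE),
    topologies = data.frame(
      topology = topo_keys,
      percent = 100 * unname(topo_counts) / sample$n,
      stringsAsFactors = FALSE))
}

#' Support for a partial split
#'
#' The percentage of trees whose induced subtree on a taxon subset displays
#' a given clade: each tree is pruned to the subset (retaining its rooting)
#' and the clade is checked on the pruned tree. With the subset equal to the
#' full leaf set this reduces to full-split support.
#'
#' @param sample a [tree_sample()] of rooted trees.
#' @param clade character vector, the clade of interest.
#' @param taxa taxon subset defining the partial problem (must contain
#'   \code{clade}); default all leaves.
#' @return list with \code{percent}, \code{kind} ("full" or "partial") and
#'   \code{informative} (FALSE when the induced problem is trivial).
#' @export
partial_split_support <- function(sample, clade, taxa = sample$leaves) {
  stopifnot(inherits(sample, "tree_sample"))
  clade <- sort(clade); taxa <- sort(taxa)
  if (!all(clade %in% taxa)) stop("clade must be a subset of taxa")
  if (!all(taxa %in% sample$leaves)) stop("taxa must be within the leaf set")
  kind <- if (identical(taxa, sample$leaves)) "full" else "partial"
  if (length(taxa) < 3L || length(clade) < 2L || length(clade) >= length(taxa))
    return(list(percent = 100, kind = kind, informative = FALSE))
  key <- clade_key(clade)
  supp <- vapply(sample$trees, function(t) {
    pt <- if (kind == "partial") ape::keep.tip(t, taxa) else t
    key %in% tree_clade_keys(pt)
  }, logical(1))
  list(percent = 100 * mean(supp), kind = kind, informative = TRUE)
}

#' Clade-support table across analyses
#'
#' One row per tree sample (analysis), one column per possible clade on the
#' shared reduced leaf set; percentages to one decimal, zeros rendered as
#' \code{"-"}.
#'
#' @param samples named list of [tree_sample()] objects reduced to the same
#'   leaf set.
#' @return character data.frame; the unrounded numeric matrix is attached as
#'   attribute \code{"percent"}.
#' @export
support_table <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 1L)
  if (is.null(names(samples)))
    names(samples) <- vapply(samples, `[[`, character(1), "source")
  leaves <- samples[[1]]$leaves
  for (nm in names(samples))
    if (!identical(samples[[nm]]$leaves, leaves))
      stop("sample '", nm, "' is not on the shared leaf set")
  clades <- enumerate_clades(leaves)
  single <- all(nchar(leaves) == 1L)
  col_lab <- vapply(clades, function(s)
    paste(s, collapse = if (single) "" else "+"), character(1))
  pct <- matrix(NA_real_, length(samples), length(clades),
                dimnames = list(names(samples), col_lab))
  for (nm in names(samples)) {
    supp <- full_split_support(samples[[nm]])
    pct[nm, ] <- supp$clades$percent
  }
  txt <- ifelse(pct == 0, "-", sprintf("%.1f", round_half_up(pct, 1)))
  out <- as.data.frame(txt, stringsAsFactors = FALSE)
  attr(out, "percent") <- pct
  out
}
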