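#' Simulate a tree sample with controlled split frequencies
#'
#' Draws rooted binary topologies i.i.d. from a distribution over the full
#' enumerated topology set, either given directly or solved for from target
#' clade frequencies. Empirical clade frequencies converge to their targets
#' as the number of trees grows, which makes the output a controlled fixture
#' for split-support summaries.
#'
#' @param leaves labels or a single integer n (see
#'   [enumerate_rooted_trees()]).
#' @param n_trees number of trees to draw.
#' @param topology_probs named numeric vector of probabilities; names are
#'   newick strings of rooted topologies (canonicalised internally).
#'   Unlisted topologies get probability 0.
#' @param clade_targets named numeric vector of target clade frequencies in
#'   [0, 1]; names are comma-separated taxon lists (e.g. \code{"A,B"}). A
#'   distribution over topologies matching the targets is found by
#'   non-negative least squares; targets no distribution can realise are
#'   rejected with a diagnostic.
#' @param seed RNG seed.
#' @param tol tolerance on the realised clade frequencies when solving from
#'   \code{clade_targets}.
#' @return A [tree_sample()]; the generating distribution is attached as
#'   attribute \code{"topology_probs"}.
#' @export
simulate_treeset <- function(leaves, n_trees, topology_probs = NULL,
                             clade_targets = NULL, seed = NULL,
                             tol = 1e-6) {
  if (is.numeric(leaves) && length(leaves) == 1L)
    leaves <- LETTERS[seq_len(leaves)]
  topos <- enumerate_rooted_trees(leaves)
  if (is.null(topology_probs) == is.null(clade_targets))
    stop("supply exactly one of topology_probs or clade_targets")

  if (!is.null(topology_probs)) {
    stop_if_not_prob(topology_probs, "topology_probs")
    keys <- vapply(names(topology_probs), function(s) {
      t <- ape::read.tree(text = paste0(sub(";\\s*$", "", s), ";"))
      topology_key(t)
    }, character(1))
    if (!all(keys %in% topos))
      stop("topology_probs names include a tree not on the given leaf set")
    p <- stats::setNames(numeric(length(topos)), topos)
    for (i in seq_along(keys)) p[keys[i]] <- p[keys[i]] + topology_probs[i]
    if (abs(sum(p) - 1) > 1e-8) stop("topology_probs must sum to 1")
  } else {
    stop_if_not_prob(clade_targets, "clade_targets")
    target_sets <- lapply(strsplit(names(clade_targets), ","), trimws)
    if (!all(unlist(target_sets) %in% leaves))
      stop("clade_targets name taxa outside the leaf set")
    ## incidence: M[c, t] = 1 if topology t contains clade c
    M <- vapply(topos, function(tp) {
      ck <- tree_clade_keys(
        ape::read.tree(text = paste0(tp, ";")))
      vapply(target_sets, function(s) clade_key(s) %in% ck, numeric(1))
    }, numeric(length(target_sets)))
    M <- matrix(M, nrow = length(target_sets))
    ## min ||Mp - f|| s.t. p >= 0, sum(p) = 1 (heavily weighted constraint)
    w <- 1e3
    A <- rbind(M, rep(w, length(topos)))
    b <- c(unname(clade_targets), w)
    p <- pracma::lsqnonneg(A, b)$x
    p <- p / sum(p)
    achieved <- as.vector(M %*% p)
    if (max(abs(achieved - unname(clade_targets))) > max(tol, 1e-6))
      stop(sprintf(paste0(
        "no distribution over rooted topologies realises these clade ",
        "frequencies (closest achievable: %s)"),
        paste(sprintf("%s=%.4f", names(clade_targets), achieved),
              collapse = ", ")))
    p <- stats::setNames(p, topos)
  }

  with_seed(seed, {
    idx <- sample.int(length(topos), n_trees, replace = TRUE, prob = p)
    trees <- lapply(topos[idx], function(s)
      ape::read.tree(text = paste0(s, ";")))
    out <- tree_sample(trees, "simulated")
    attr(out, "topology_probs") <- p
    out
  })
}
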