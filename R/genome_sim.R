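#' Circular genome object
#'
#' A lightweight container for a circular nucleotide sequence. Coordinates on
#' the circle are 0-based; coordinate 0 is whatever the caller makes it (for
#' vertebrate mitogenomes a common convention is the start of the
#' \emph{trnF} tRNA gene).
#'
#' @param id taxon/specimen label.
#' @param seq nucleotide string over A/C/G/T.
#' @return An object of class \code{circular_genome} with fields \code{id},
#'   \code{seq}, \code{length}.
#' @export
circular_genome <- function(id, seq) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) < 1L) stop("genome sequence must be non-empty")
  if (grepl("[^ACGT]", seq)) stop("genome sequence must contain only A/C/G/T")
  structure(list(id = id, seq = seq, length = nchar(seq)),
            class = "circular_genome")
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %d bp, GC %.1f%%\n",
              x$id, x$length, gc_percent(x$seq)))
  invisible(x)
}

#' Substitution model for genome simulation
#'
#' Either a stationary GTR model or an F81-style model; per-lineage target
#' base frequencies can be supplied to drive non-reversible compositional
#' drift (each listed branch evolves towards its own composition), which is
#' the mechanism used to generate base-composition heterogeneity across taxa.
#'
#' @param type \code{"f81"} or \code{"gtr"}.
#' @param base_freqs length-4 numeric (A, C, G, T), summing to 1.
#' @param rates length-6 GTR exchangeabilities (AC, AG, AT, CG, CT, GT);
#'   ignored for \code{"f81"}.
#' @param lineage_freqs optional named list mapping a node label (tip label,
#'   or internal node label) to a length-4 target frequency vector; the
#'   branch subtending that node uses an F81 process towards those
#'   frequencies instead of the global model.
#' @export
substitution_model <- function(type = c("f81", "gtr"),
                               base_freqs = rep(0.25, 4),
                               rates = rep(1, 6),
                               lineage_freqs = NULL) {
  type <- match.arg(type)
  base_freqs <- as.numeric(base_freqs)
  if (length(base_freqs) != 4L || abs(sum(base_freqs) - 1) > 1e-8)
    stop("base_freqs must be 4 values summing to 1")
  stop_if_not_prob(base_freqs, "base_freqs")
  if (!is.null(lineage_freqs)) {
    for (f in lineage_freqs)
      if (length(f) != 4L || abs(sum(f) - 1) > 1e-8)
        stop("each lineage_freqs entry must be 4 values summing to 1")
  }
  structure(list(type = type, base_freqs = base_freqs, rates = rates,
                 lineage_freqs = lineage_freqs),
            class = "substitution_model")
}

#' Evolution specification for the genome simulator
#'
#' @param tree an \code{ape::phylo} tree (or newick string) with branch
#'   lengths in expected substitutions per site.
#' @param model a [substitution_model()].
#' @param indel_rate indel events per site per unit branch length.
#' @param seed integer RNG seed, or NULL.
#' @export
evolution_spec <- function(tree, model = substitution_model(),
                           indel_rate = 0, seed = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object or newick")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  if (length(tree$tip.label) < 2L) stop("tree must have >= 2 leaves")
  if (indel_rate < 0) stop("indel_rate must be >= 0")
  structure(list(tree = tree, model = model, indel_rate = indel_rate,
                 seed = seed),
            class = "evolution_spec")
}

## F81 transition matrix towards target frequencies pi, scaled so that one
## unit of branch length is one expected substitution/site at stationarity.
f81_pmatrix <- function(t, pi) {
  mu <- 1 / (1 - sum(pi^2))
  e <- exp(-mu * t)
  P <- matrix(rep(pi, each = 4L), 4L, 4L)
  P <- (1 - e) * P
  diag(P) <- diag(P) + e
  dimnames(P) <- list(BASES, BASES)
  P
}

## GTR transition matrix via spectral decomposition of the pi-symmetrised
## rate matrix. rates order: AC, AG, AT, CG, CT, GT.
gtr_pmatrix <- function(t, pi, rates) {
  R <- matrix(0, 4, 4)
  R[1, 2] <- R[2, 1] <- rates[1]
  R[1, 3] <- R[3, 1] <- rates[2]
  R[1, 4] <- R[4, 1] <- rates[3]
  R[2, 3] <- R[3, 2] <- rates[4]
  R[2, 4] <- R[4, 2] <- rates[5]
  R[3, 4] <- R[4, 3] <- rates[6]
  Q <- R %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  ## symmetrise: S = D^{1/2} Q D^{-1/2} is symmetric for reversible Q
  d <- sqrt(pi)
  S <- diag(d) %*% Q %*% diag(1 / d)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  P <- diag(1 / d) %*% es$vectors %*% diag(exp(es$values * t)) %*%
    t(es$vectors) %*% diag(d)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(BASES, BASES)
  P
}

## Evolve a vector of base indices (1..4) through transition matrix P.
mutate_states <- function(states, P) {
  out <- states
  for (s in 1:4) {
    idx <- which(states == s)
    if (length(idx))
      out[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[s, ])
  }
  out
}

## Apply indel events to a (states, ids) pair. ids are real-valued column
## identifiers; insertions get ids interpolated between their neighbours so
## that the final true alignment is recovered by sorting ids.
apply_indels <- function(states, ids, n_events, base_freqs) {
  for (i in seq_len(n_events)) {
    L <- length(states)
    if (L < 10L) break
    len <- min(stats::rgeom(1, 0.5) + 1L, 10L)
    if (stats::runif(1) < 0.5) {             # deletion
      pos <- sample.int(L - len + 1L, 1L)
      keep <- setdiff(seq_len(L), pos:(pos + len - 1L))
      states <- states[keep]; ids <- ids[keep]
    } else {                                 # insertion
      pos <- sample.int(L + 1L, 1L)          # insert before position pos
      lo <- if (pos == 1L) ids[1] - 1 else ids[pos - 1L]
      hi <- if (pos > L) ids[L] + 1 else ids[pos]
      newids <- lo + (hi - lo) * sort(stats::runif(len, 0.05, 0.95))
      newstates <- sample.int(4L, len, replace = TRUE, prob = base_freqs)
      states <- append(states, newstates, after = pos - 1L)
      ids <- append(ids, newids, after = pos - 1L)
    }
  }
  list(states = states, ids = ids)
}

#' Simulate circular genomes on a tree, with the true alignment
#'
#' Evolves a root genome along a rooted tree under a simple nucleotide
#' substitution model (optionally with lineage-specific compositional drift
#' and indels) and returns one circular genome per leaf plus the true
#' multiple alignment implied by the simulated indel history, so downstream
#' windowing can run without an aligner.
#'
#' @param spec an [evolution_spec()].
#' @param root_genome_length length of the root genome in bases.
#' @return list with \code{genomes} (named list of [circular_genome()]),
#'   \code{alignment} (character matrix, rows = leaves, \code{"-"} for
#'   gaps), \code{tree}, and \code{max_p_distance} (achieved maximum
#'   pairwise p-distance among the leaves).
#' @export
simulate_genomes <- function(spec, root_genome_length) {
  stopifnot(inherits(spec, "evolution_spec"))
  if (!is.numeric(root_genome_length) || root_genome_length < 1)
    stop("root_genome_length must be a positive number of bases")
  L0 <- as.integer(root_genome_length)
  tree <- spec$tree
  model <- spec$model

  with_seed(spec$seed, {
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    nodes <- vector("list", ntip + tree$Nnode)
    nodes[[root]] <- list(
      states = sample.int(4L, L0, replace = TRUE, prob = model$base_freqs),
      ids = as.numeric(seq_len(L0)))

    node_label <- function(v) {
      if (v <= ntip) tree$tip.label[v]
      else if (!is.null(tree$node.label)) tree$node.label[v - ntip]
      else NA_character_
    }

    edges <- ape::reorder.phylo(tree, "cladewise")$edge
    eln <- tree$edge.length[match(paste(edges[, 1], edges[, 2]),
                                  paste(tree$edge[, 1], tree$edge[, 2]))]
    for (e in seq_len(nrow(edges))) {
      par <- edges[e, 1]; child <- edges[e, 2]; t <- eln[e]
      st <- nodes[[par]]
      lab <- node_label(child)
      lf <- if (!is.na(lab)) model$lineage_freqs[[lab]] else NULL
      P <- if (!is.null(lf)) f81_pmatrix(t, lf)
           else if (model$type == "gtr") gtr_pmatrix(t, model$base_freqs,
                                                     model$rates)
           else f81_pmatrix(t, model$base_freqs)
      states <- if (t > 0) mutate_states(st$states, P) else st$states
      ids <- st$ids
      if (spec$indel_rate > 0 && t > 0) {
        nev <- stats::rpois(1, spec$indel_rate * t * length(states))
        r <- apply_indels(states, ids, nev, model$base_freqs)
        states <- r$states; ids <- r$ids
      }
      nodes[[child]] <- list(states = states, ids = ids)
    }

    all_ids <- sort(unique(unlist(lapply(seq_len(ntip),
                                         function(i) nodes[[i]]$ids))))
    aln <- matrix("-", nrow = ntip, ncol = length(all_ids),
                  dimnames = list(tree$tip.label, NULL))
    genomes <- vector("list", ntip)
    names(genomes) <- tree$tip.label
    for (i in seq_len(ntip)) {
      chars <- BASES[nodes[[i]]$states]
      aln[i, match(nodes[[i]]$ids, all_ids)] <- chars
      genomes[[i]] <- circular_genome(tree$tip.label[i],
                                      paste(chars, collapse = ""))
    }
    maxpd <- if (ntip >= 2) max(p_distance_matrix(aln), na.rm = TRUE) else 0
    list(genomes = genomes, alignment = aln, tree = tree,
         max_p_distance = maxpd)
  })
}
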