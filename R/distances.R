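## LogDet/paralinear distance from a 4x4 joint count matrix.
## d = -1/4 [ ln det(F) - 1/2 ln(det Dx * det Dy) ], F the joint relative
## frequency matrix, Dx/Dy diagonal matrices of the marginal frequencies.
logdet_from_joint <- function(J) {
  n <- sum(J)
  if (n == 0) return(NA_real_)
  F <- J / n
  fx <- rowSums(F); fy <- colSums(F)
  if (any(fx == 0) || any(fy == 0)) return(NA_real_)
  dF <- det(F)
  if (!is.finite(dF) || dF <= 0) return(NA_real_)
  -0.25 * (log(dF) - 0.5 * (sum(log(fx)) + sum(log(fy))))
}

#' LogDet (paralinear) distance between two aligned sequences
#'
#' Determinant-based distance that remains additive under non-stationary,
#' non-homogeneous base composition, unlike corrections built on the
#' p-distance. Columns where either sequence carries a gap, N or ambiguity
#' code are excluded (pairwise deletion). The -1/4 scaling (4-state
#' convention) is used; rescale if comparing with software using the
#' unscaled paralinear form.
#'
#' @param x,y aligned sequences (strings or per-column character vectors).
#' @return nonnegative distance; 0 for identical sequences; NA (with an
#'   attribute \code{"reason"}) when the joint matrix is singular, e.g. a
#'   base entirely absent from one sequence.
#' @export
logdet_distance <- function(x, y) {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "", fixed = TRUE)[[1]]
  if (length(y) == 1L && nchar(y) > 1L) y <- strsplit(y, "", fixed = TRUE)[[1]]
  if (length(x) != length(y)) stop("sequences must be aligned (equal length)")
  x <- toupper(x); y <- toupper(y)
  ok <- x %in% BASES & y %in% BASES
  if (!any(ok)) stop("no usable (gap/N-free) columns")
  J <- table(factor(x[ok], levels = BASES), factor(y[ok], levels = BASES))
  d <- logdet_from_joint(unclass(J))
  if (is.na(d)) attr(d, "reason") <- "singular joint frequency matrix"
  d
}

#' Pairwise distance matrix of an alignment
#'
#' @param aln alignment (character matrix, strings, or DNAbin).
#' @param method \code{"p"} or \code{"logdet"}.
#' @return symmetric matrix with zero diagonal and attribute
#'   \code{"method"}; LogDet entries may be NA where the divergence matrix
#'   is singular.
#' @export
distance_matrix <- function(aln, method = c("p", "logdet")) {
  method <- match.arg(method)
  aln <- as_aln_matrix(aln)
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  if (n >= 2L)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- if (method == "p") p_distance(aln[i, ], aln[j, ])
                            else as.numeric(logdet_distance(aln[i, ],
                                                            aln[j, ]))
  attr(d, "method") <- method
  d
}

#' Chi-square test of base-composition homogeneity across taxa
#'
#' The classic contingency-table test on the taxa x base count table built
#' from non-gap, non-N sites: under homogeneity the expected count in each
#' cell is (row total x column total) / grand total, the statistic is
#' \eqn{\sum (O - E)^2 / E} and the degrees of freedom are
#' (taxa - 1)(bases - 1). Bases absent from every taxon are dropped with
#' the df adjusted.
#'
#' @param aln alignment (character matrix, strings, or DNAbin).
#' @return list of class \code{composition_test}: \code{table},
#'   \code{statistic}, \code{df}, \code{p_value}.
#' @export
composition_chi2 <- function(aln) {
  aln <- as_aln_matrix(aln)
  if (nrow(aln) < 2L) stop("need >= 2 taxa")
  tab <- t(apply(aln, 1, function(r)
    table(factor(r[r %in% BASES], levels = BASES))))
  colnames(tab) <- BASES
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  structure(list(table = tab, statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "composition_test")
}

#' @export
print.composition_test <- function(x, ...) {
  cat(sprintf(
    "Base-composition homogeneity: X-squared = %.3f, df = %d, p = %.4g\n",
    x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Minimum-evolution tree from a distance matrix
#'
#' Builds an unrooted tree by neighbor joining, the standard heuristic for
#' the minimum-evolution criterion. On an additive matrix the tree's path
#' lengths reproduce the input distances exactly.
#'
#' @param dm symmetric distance matrix (e.g. from [distance_matrix()]).
#' @return an unrooted \code{phylo} with branch lengths.
#' @export
nj_me_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (any(is.na(dm))) {
    bad <- which(is.na(dm), arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    stop("undefined distances for pairs: ",
         paste(apply(bad, 1, function(r)
           paste(rownames(dm)[r[1]], colnames(dm)[r[2]], sep = "-")),
           collapse = ", "))
  }
  if (nrow(dm) < 3L) stop("need >= 3 taxa")
  ape::nj(stats::as.dist(dm))
}

#' Nonparametric bootstrap over alignment columns
#'
#' Resamples alignment columns with replacement, computes the chosen
#' distance matrix per replicate and builds one NJ/minimum-evolution tree
#' per replicate. Replicates whose distance matrix has undefined (singular
#' LogDet) entries are redrawn, with the redraw count recorded.
#'
#' @param aln alignment (character matrix, strings, or DNAbin).
#' @param n_reps number of bootstrap replicates.
#' @param method distance used per replicate: \code{"logdet"} or \code{"p"}.
#' @param seed RNG seed.
#' @param source label for the resulting [tree_sample()].
#' @return a [tree_sample()] of unrooted trees (root before computing clade
#'   support); attribute \code{"n_redrawn"} counts redrawn replicates.
#' @export
bootstrap_trees <- function(aln, n_reps, method = c("logdet", "p"),
                            seed = NULL, source = "bootstrap") {
  method <- match.arg(method)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  aln <- as_aln_matrix(aln)
  ntax <- nrow(aln); L <- ncol(aln)
  if (ntax < 3L) stop("need >= 3 taxa")
  taxa <- rownames(aln) %||% paste0("t", seq_len(ntax))
  rownames(aln) <- taxa
  ## per-pair column codes: 1..16 joint base pattern, 0 = pairwise-deleted
  pairs <- utils::combn(ntax, 2)
  codes <- matrix(0L, ncol(pairs), L)
  base_i <- function(r) {
    i <- match(aln[r, ], BASES)
    i[is.na(i)] <- 0L
    i
  }
  bi <- lapply(seq_len(ntax), base_i)
  for (p in seq_len(ncol(pairs))) {
    a <- bi[[pairs[1, p]]]; b <- bi[[pairs[2, p]]]
    ok <- a > 0L & b > 0L
    codes[p, ok] <- (a[ok] - 1L) * 4L + b[ok]
  }
  with_seed(seed, {
    trees <- vector("list", n_reps)
    n_redrawn <- 0L
    r <- 1L
    guard <- 0L
    while (r <= n_reps) {
      guard <- guard + 1L
      if (guard > 50L * n_reps + 100L)
        stop("too many degenerate bootstrap replicates")
      w <- tabulate(sample.int(L, L, replace = TRUE), L)
      d <- matrix(0, ntax, ntax, dimnames = list(taxa, taxa))
      bad <- FALSE
      for (p in seq_len(ncol(pairs))) {
        cp <- codes[p, ]
        use <- cp > 0L & w > 0L
        cnt <- numeric(16)
        if (any(use)) {
          agg <- rowsum(w[use], cp[use])
          cnt[as.integer(rownames(agg))] <- agg[, 1]
        }
        J <- matrix(cnt, 4, 4, byrow = TRUE)
        dd <- if (method == "logdet") logdet_from_joint(J)
              else if (sum(J) > 0) 1 - sum(diag(J)) / sum(J)
              else NA_real_
        if (is.na(dd)) { bad <- TRUE; break }
        d[pairs[1, p], pairs[2, p]] <- d[pairs[2, p], pairs[1, p]] <- dd
      }
      if (bad) { n_redrawn <- n_redrawn + 1L; next }
      trees[[r]] <- nj_me_tree(d)
      r <- r + 1L
    }
    out <- tree_sample(trees, source)
    attr(out, "n_redrawn") <- n_redrawn
    out
  })
}
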