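#' Pairwise p-distance
#'
#' Proportion of differing sites between two aligned sequences. Columns
#' where either sequence has a gap, N or any non-ACGT symbol are excluded
#' (pairwise deletion).
#'
#' @param a,b aligned sequences: character scalars or per-column character
#'   vectors of equal length.
#' @return fraction in [0, 1]; NA if no usable columns remain.
#' @export
p_distance <- function(a, b) {
  if (length(a) == 1L && nchar(a) > 1L) a <- strsplit(a, "", fixed = TRUE)[[1]]
  if (length(b) == 1L && nchar(b) > 1L) b <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  a <- toupper(a); b <- toupper(b)
  ok <- a %in% BASES & b %in% BASES
  if (!any(ok)) return(NA_real_)
  mean(a[ok] != b[ok])
}

#' All pairwise p-distances of an alignment
#' @param aln character matrix (rows = taxa) or list/vector of equal-length
#'   strings.
#' @return symmetric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(aln) {
  aln <- as_aln_matrix(aln)
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  if (n < 2L) return(d)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- p_distance(aln[i, ], aln[j, ])
  d
}

## Coerce strings / DNAbin / matrix to an upper-case character matrix.
as_aln_matrix <- function(aln) {
  if (inherits(aln, "DNAbin")) aln <- toupper(as.character(aln))
  if (is.character(aln) && !is.matrix(aln)) {
    if (length(unique(nchar(aln))) != 1L)
      stop("alignment rows must have equal length")
    aln <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  }
  if (!is.matrix(aln)) stop("cannot interpret alignment")
  toupper(aln)
}

#' Sliding-window maximum p-distance profile
#'
#' For each window start, the maximum over all taxon pairs of the p-distance
#' within the window. On circular alignments windows wrap past the end.
#'
#' @param aln alignment (character matrix, strings, or DNAbin).
#' @param window_len window length in columns.
#' @param step step between window starts.
#' @param circular wrap windows past the alignment end?
#' @return data.frame with \code{start} (0-based window start column) and
#'   \code{max_p_distance}.
#' @export
sliding_pdistance_profile <- function(aln, window_len, step = 1,
                                      circular = TRUE) {
  aln <- as_aln_matrix(aln)
  L <- ncol(aln); n <- nrow(aln)
  if (window_len < 1 || step < 1) stop("window_len and step must be >= 1")
  if (!circular && window_len > L)
    stop("window_len exceeds alignment length on a linear alignment")
  window_len <- min(window_len, L)
  ext <- if (circular) cbind(aln, aln[, seq_len(window_len - 1), drop = FALSE])
         else aln
  starts <- seq(1L, if (circular) L else L - window_len + 1L, by = step)
  maxpd <- rep(0, length(starts))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    x <- ext[i, ]; y <- ext[j, ]
    ok <- (x %in% BASES) & (y %in% BASES)
    df <- as.integer(ok & x != y)
    okc <- c(0L, cumsum(as.integer(ok))); dfc <- c(0L, cumsum(df))
    e <- starts + window_len - 1L
    nok <- okc[e + 1L] - okc[starts]
    ndf <- dfc[e + 1L] - dfc[starts]
    p <- ifelse(nok > 0L, ndf / nok, 0)
    maxpd <- pmax(maxpd, p)
  }
  data.frame(start = starts - 1L, max_p_distance = maxpd)
}

#' Partition a divergence profile into homogeneous windows
#'
#' Greedy change-point segmentation: a new block is opened whenever adding
#' the next profile value would push the within-block range of maximum
#' p-distance above \code{range_tol} (and the current block has reached
#' \code{min_block} columns). Block boundaries are then widened so every
#' consecutive pair of windows — including last-to-first on a circular
#' alignment — overlaps by \code{min_overlap} columns, so no read sitting on
#' a boundary can be lost by windowed extraction.
#'
#' @param profile output of [sliding_pdistance_profile()] (or a numeric
#'   vector of per-start values with step 1).
#' @param min_block minimum block length (columns).
#' @param min_overlap overlap between consecutive windows (columns).
#' @param range_tol within-block divergence range allowed.
#' @param circular treat the alignment as circular.
#' @param aln_length alignment length in columns (inferred from the profile
#'   when omitted; required if the profile does not start at 0/step 1).
#' @return data.frame of windows with 0-based half-open \code{start},
#'   \code{end} (wrap allowed: the final circular window may have
#'   \code{end < start}).
#' @export
partition_by_divergence <- function(profile, min_block, min_overlap,
                                    range_tol = 0.05, circular = TRUE,
                                    aln_length = NULL) {
  if (is.data.frame(profile)) {
    starts <- profile$start; vals <- profile$max_p_distance
  } else {
    vals <- as.numeric(profile); starts <- seq_along(vals) - 1L
  }
  if (min_overlap < 0) stop("min_overlap must be >= 0")
  step <- if (length(starts) > 1L) starts[2] - starts[1] else 1L
  L <- aln_length %||% (max(starts) + step)
  if (L <= min_block)
    return(data.frame(start = 0L, end = if (circular) 0L else L))

  bounds <- starts[1]
  blo <- bhi <- vals[1]
  bstart <- starts[1]
  for (k in seq_along(vals)[-1]) {
    nlo <- min(blo, vals[k]); nhi <- max(bhi, vals[k])
    if ((nhi - nlo) > range_tol && (starts[k] - bstart) >= min_block) {
      bounds <- c(bounds, starts[k])
      bstart <- starts[k]; blo <- bhi <- vals[k]
    } else {
      blo <- nlo; bhi <- nhi
    }
  }
  bounds <- c(bounds, L)
  ## merge a trailing runt block into its predecessor
  nb <- length(bounds)
  if (nb > 2L && (bounds[nb] - bounds[nb - 1L]) < min_block)
    bounds <- bounds[-(nb - 1L)]

  m <- length(bounds) - 1L
  start <- bounds[seq_len(m)]
  end <- bounds[seq_len(m) + 1L] + min_overlap
  if (circular) {
    end <- end %% L
    if (m == 1L) end <- start  # single window spans the whole circle
  } else {
    end <- pmin(end, L)
  }
  data.frame(start = as.integer(start), end = as.integer(end))
}

#' Validate a set of circular windows
#'
#' Reports the minimum overlap between consecutive windows (including the
#' wrap-around pair on a circular alignment) and whether the windows jointly
#' cover the alignment.
#'
#' @param windows data.frame with 0-based half-open \code{start},
#'   \code{end} columns (wrap allowed: \code{end <= start} means the window
#'   crosses the origin).
#' @param min_overlap required overlap (bp); reported as
#'   \code{meets_min_overlap}.
#' @param circular_length alignment length (circle size).
#' @return list: \code{min_consecutive_overlap} (NA for a single window,
#'   where self-adjacency makes overlap not applicable),
#'   \code{covers_alignment}, \code{meets_min_overlap}, \code{overlaps}.
#' @export
validate_windows <- function(windows, min_overlap, circular_length) {
  stopifnot(is.data.frame(windows), nrow(windows) >= 1L)
  L <- circular_length
  s <- windows$start; e <- windows$end
  e <- ifelse(e > s, e, e + L)
  if (any(s < 0 | s >= L)) stop("window starts must lie in [0, L)")
  o <- order(s)
  s <- s[o]; e <- e[o]
  n <- length(s)
  if (n == 1L) {
    covers <- (e - s) >= L
    return(list(min_consecutive_overlap = NA_real_,
                covers_alignment = covers,
                meets_min_overlap = NA, overlaps = numeric(0)))
  }
  overlaps <- e[-n] - s[-1]
  ## the wrap pair only exists when the final window crosses the origin
  if (e[n] > L) overlaps <- c(overlaps, e[n] - (s[1] + L))
  runmax <- cummax(e)
  gaps_ok <- all(s[-1] <= runmax[-n]) &&
    (runmax[n] >= s[1] + L || (s[1] == 0 && runmax[n] >= L))
  list(min_consecutive_overlap = min(overlaps),
       covers_alignment = gaps_ok,
       meets_min_overlap = min(overlaps) >= min_overlap,
       overlaps = overlaps)
}

#' Majority-rule consensus of an alignment window
#'
#' Per-column majority base over the window; ties produce IUPAC ambiguity
#' codes; columns where gaps hold a strict majority (including all-gap
#' columns) are dropped, so the consensus is gap-free and usable as a
#' mapping reference.
#'
#' @param aln alignment (character matrix, strings, or DNAbin).
#' @param start,end 0-based half-open window on the alignment columns, wrap
#'   allowed (\code{end <= start} crosses the origin). Defaults to the full
#'   alignment.
#' @return consensus sequence (character scalar, no gaps).
#' @export
window_consensus <- function(aln, start = 0L, end = 0L) {
  aln <- as_aln_matrix(aln)
  L <- ncol(aln)
  start <- as.integer(start) %% L
  end <- as.integer(end) %% L
  cols <- if (end > start) (start + 1L):end
          else if (end == start) (((start:(start + L - 1L)) %% L) + 1L)
          else c((start + 1L):L, seq_len(end))
  out <- character(0)
  nr <- nrow(aln)
  for (cc in cols) {
    col <- aln[, cc]
    gaps <- sum(col == "-")
    if (gaps * 2L > nr) next                       # gap-majority: drop
    tab <- table(factor(col[col %in% BASES], levels = BASES))
    if (sum(tab) == 0L) next                       # nothing informative
    top <- BASES[tab == max(tab)]
    out <- c(out, iupac_code(top))
  }
  paste(out, collapse = "")
}

#' Read-extraction mismatch threshold for a window
#'
#' Adds an allowance to the window's maximum observed divergence so that
#' every read of the target taxa clears the bar. The default reading of a
#' "10\% allowance" is additive percentage points (0.22 -> 0.32); a
#' multiplicative mode (0.22 -> 0.242) is available.
#'
#' @param max_p_distance window maximum pairwise p-distance in [0, 1].
#' @param allowance additional allowance in [0, 1].
#' @param mode \code{"additive"} (default) or \code{"multiplicative"}.
#' @return threshold in [0, 1] (capped at 1).
#' @export
compute_threshold <- function(max_p_distance, allowance = 0.10,
                              mode = c("additive", "multiplicative")) {
  mode <- match.arg(mode)
  stop_if_not_prob(max_p_distance, "max_p_distance")
  stop_if_not_prob(allowance, "allowance")
  t <- switch(mode,
              additive = max_p_distance + allowance,
              multiplicative = max_p_distance * (1 + allowance))
  pmin(t, 1)
}

#' Per-window summary table (divergence, threshold, consensus)
#'
#' Convenience wrapper that computes, for each window, the maximum pairwise
#' p-distance, the derived extraction threshold, and the gap-free consensus.
#'
#' @inheritParams window_consensus
#' @param windows data.frame with \code{start}, \code{end}.
#' @inheritParams compute_threshold
#' @return data.frame: start, end, max_p_distance, threshold, consensus.
#' @export
window_table <- function(aln, windows, allowance = 0.10,
                         mode = c("additive", "multiplicative")) {
  mode <- match.arg(mode)
  aln <- as_aln_matrix(aln)
  L <- ncol(aln)
  res <- lapply(seq_len(nrow(windows)), function(i) {
    s <- windows$start[i]; e <- windows$end[i]
    cols <- if (e > s) (s + 1L):e
            else if (e == s) (((s:(s + L - 1L)) %% L) + 1L)
            else c((s + 1L):L, seq_len(e))
    sub <- aln[, cols, drop = FALSE]
    mpd <- max(p_distance_matrix(sub), na.rm = TRUE)
    data.frame(start = s, end = e, max_p_distance = mpd,
               threshold = compute_threshold(mpd, allowance, mode),
               consensus = window_consensus(sub, 0L, ncol(sub)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
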