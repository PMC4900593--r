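#' Rotate a linear representation of a circular sequence
#'
#' Moves the final \code{k} bases of \code{ref} to the front, i.e. shifts the
#' coordinate origin of the underlying circle backwards by \code{k} bases.
#' Running an assembly against both the original and a rotated reference is
#' the standard workaround for the edge artifact that linearising a circular
#' genome creates at the reference ends.
#'
#' @param ref character scalar, the sequence.
#' @param k integer, number of terminal bases to move to the front
#'   (\code{0 <= k <= nchar(ref)}).
#' @return The rotated sequence (same length).
#' @examples
#' rotate_reference("ABCDEFGH", 3)  # "FGHABCDE"
#' @export
rotate_reference <- function(ref, k) {
  stopifnot(is.character(ref), length(ref) == 1L)
  n <- nchar(ref)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0 || k > n)
    stop("k must be a single integer in [0, nchar(ref)]")
  k <- as.integer(k)
  if (k == 0L || k == n) return(ref)
  paste0(substr(ref, n - k + 1L, n), substr(ref, 1L, n - k))
}

#' Extract a substring from a circular sequence
#'
#' Coordinates are 0-based and half-open; intervals may wrap past the origin
#' (\code{start >= end} means the interval crosses coordinate 0).
#'
#' @param seq character scalar.
#' @param start 0-based start (inclusive).
#' @param len length of the substring in bases (must be <= nchar(seq)).
#' @return character scalar of length \code{len}.
#' @export
circular_substring <- function(seq, start, len) {
  n <- nchar(seq)
  stopifnot(len >= 0, len <= n)
  start <- ((as.integer(start) %% n) + n) %% n
  if (start + len <= n) return(substr(seq, start + 1L, start + len))
  paste0(substr(seq, start + 1L, n), substr(seq, 1L, start + len - n))
}

## Length of the circular interval [start, end) on a circle of size L.
circ_interval_length <- function(start, end, L) {
  d <- (end - start) %% L
  ifelse(d == 0, L, d)
}

## Locate `probe` (a prefix/segment of one linearisation) on the circle of
## `target`, tolerating a bounded mismatch fraction, and return the 0-based
## offset on target where probe starts, or NA. Used to derotate two
## reconstructions of the same circle to a shared origin.
find_circular_offset <- function(target, probe, max_mismatch_frac = 0.2) {
  doubled <- paste0(target, target)
  m <- Biostrings::matchPattern(
    Biostrings::DNAString(probe), Biostrings::DNAString(doubled),
    max.mismatch = ceiling(max_mismatch_frac * nchar(probe)),
    fixed = FALSE)
  if (length(m) == 0L) return(NA_integer_)
  starts <- Biostrings::start(m)
  ## prefer the earliest hit inside the first copy
  s <- starts[starts <= nchar(target)]
  if (length(s) == 0L) s <- starts
  as.integer(s[1] - 1L) %% nchar(target)
}
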