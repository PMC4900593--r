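## Shared internal helpers.

BASES <- c("A", "C", "G", "T")

## IUPAC code for a set of bases (sorted, unique). Used for consensus ties.
IUPAC <- c(
  "A" = "A", "C" = "C", "G" = "G", "T" = "T",
  "AC" = "M", "AG" = "R", "AT" = "W", "CG" = "S", "CT" = "Y", "GT" = "K",
  "ACG" = "V", "ACT" = "H", "AGT" = "D", "CGT" = "B", "ACGT" = "N"
)

iupac_code <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  code <- IUPAC[key]
  if (is.na(code)) "N" else unname(code)
}

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG state. seed = NULL leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Half-up decimal rounding (printed-table convention; base round() is
## banker's rounding).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

## Reverse complement of an ACGT(+IUPAC) character scalar.
revcomp <- function(seq) {
  chartr("ACGTMRWSYKVHDBNacgtmrwsykvhdbn",
         "TGCAKYWSRMBDHVNtgcakywsrmbdhvn",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = ""))
}

## Fast reverse complement for vectors of reads.
revcomp_many <- function(seqs) {
  vapply(seqs, revcomp, character(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(what, " must lie in [0, 1]", call. = FALSE)
  invisible(x)
}
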