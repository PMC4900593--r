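#' Align reconstructions of one specimen across platforms
#'
#' Derotates near-identical reconstructions of the same circular genome to a
#' shared origin (best circular match of a probe from the first sequence),
#' then builds a reference-anchored multiple alignment: every other
#' sequence is globally aligned to the first and insertions are opened as
#' shared gap columns.
#'
#' @param seqs named character vector (or list of \code{reconstruction}
#'   objects / [circular_genome()]s); names identify the platforms.
#' @param derotate align circular origins first (TRUE for genuine circular
#'   reconstructions).
#' @return character matrix (rows = platforms, columns = alignment), gaps
#'   as \code{"-"}.
#' @export
align_reconstructions <- function(seqs, derotate = TRUE) {
  seqs <- lapply(seqs, function(s) {
    if (inherits(s, "reconstruction") || inherits(s, "circular_genome"))
      s$seq
    else as.character(s)
  })
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    names(seqs) <- paste0("seq", seq_along(seqs))
  if (length(seqs) < 2L) stop("need >= 2 reconstructions")
  seqs <- lapply(seqs, toupper)
  ref <- seqs[[1]]

  if (derotate) {
    ## pick an unambiguous probe from the reference
    m <- regexpr("[ACGT]{120,200}", ref)
    if (m < 0) stop("reference reconstruction has no unambiguous stretch")
    p0 <- as.integer(m)                       # 1-based probe start on ref
    probe <- substr(ref, p0, p0 + attr(m, "match.length") - 1L)
    for (i in seq_along(seqs)[-1]) {
      off <- find_circular_offset(seqs[[i]], probe)
      if (is.na(off)) next                    # leave as is; alignment decides
      k <- ((p0 - 1L) - off) %% nchar(seqs[[i]])
      seqs[[i]] <- rotate_reference(seqs[[i]], k)
    }
  }

  L1 <- nchar(ref)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 2, mismatch = -3, baseOnly = FALSE)
  per_ref <- vector("list", length(seqs) - 1L)   # base (or -) at ref pos
  per_ins <- vector("list", length(seqs) - 1L)   # insertions keyed by slot
  for (i in seq_along(seqs)[-1]) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seqs[[i]]), Biostrings::DNAString(ref),
      type = "global", substitutionMatrix = submat,
      gapOpening = 5, gapExtension = 2)
    if (Biostrings::pid(al) < 50)
      stop("reconstruction '", names(seqs)[i],
           "' shares < 50% identity with '", names(seqs)[1],
           "'; likely a different specimen")
    qa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    ra <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    atref <- rep("-", L1)
    ins <- list()
    rp <- 0L
    j <- 1L
    while (j <= length(ra)) {
      if (ra[j] != "-") {
        rp <- rp + 1L
        atref[rp] <- qa[j]
        j <- j + 1L
      } else {
        run <- j
        while (run <= length(ra) && ra[run] == "-") run <- run + 1L
        ins[[as.character(rp)]] <- paste(qa[j:(run - 1L)], collapse = "")
        j <- run
      }
    }
    per_ref[[i - 1L]] <- atref
    per_ins[[i - 1L]] <- ins
  }

  slots <- sort(unique(as.integer(unlist(lapply(per_ins, names)))))
  ins_len <- vapply(slots, function(s) {
    max(vapply(per_ins, function(x)
      nchar(x[[as.character(s)]] %||% ""), integer(1)))
  }, integer(1))
  total <- L1 + sum(ins_len)
  mat <- matrix("-", nrow = length(seqs), ncol = total,
                dimnames = list(names(seqs), NULL))
  ## column position of each ref position after inserting slots
  shift <- rep(0L, L1 + 1L)                    # shift[p+1] applies after p
  if (length(slots)) {
    add <- integer(L1 + 1L)
    add[slots + 1L] <- ins_len
    shift <- cumsum(add)
  }
  ref_cols <- seq_len(L1) + shift[seq_len(L1) + 0L]
  ## note: insertion slot s occupies columns s + shift[s] + 1 .. + len
  mat[1, ref_cols] <- strsplit(ref, "", fixed = TRUE)[[1]]
  for (i in seq_along(per_ref)) {
    mat[i + 1L, ref_cols] <- per_ref[[i]]
    for (s in names(per_ins[[i]])) {
      sl <- as.integer(s)
      str <- per_ins[[i]][[s]]
      ## columns reserved for slot sl start right after ref position sl
      base_col <- if (sl >= 1L) ref_cols[sl] else 0L
      cols <- base_col + seq_len(nchar(str))
      mat[i + 1L, cols] <- strsplit(str, "", fixed = TRUE)[[1]]
    }
  }
  mat
}

#' Call phantom single nucleotides against a cross-platform consensus
#'
#' A phantom single nucleotide is a column where the focal platform's row
#' carries a base while the majority of the other rows carry a gap — the
#' insertion-type error that homopolymer-challenged chemistries produce.
#' Counts are kept per focal base; focal N calls at columns where the other
#' rows agree on a base are tallied under N; phantom columns where the base
#' nevertheless ties or beats the gap once the focal row is included are
#' reported as \code{insertions_added} (accepted into the specimen
#' consensus) and excluded from the phantom totals. Substitution-type
#' disagreements are reported separately and never counted as phantoms.
#'
#' @param mat character matrix from [align_reconstructions()].
#' @param focal_platform row name (or index) of the platform under scrutiny.
#' @return list: \code{counts} (named A,C,G,T,N), \code{insertions_added},
#'   \code{substitutions}, \code{total_bp} (ungapped focal length),
#'   \code{rate_percent}.
#' @export
call_phantoms <- function(mat, focal_platform) {
  stopifnot(is.matrix(mat))
  if (nrow(mat) < 3L)
    stop("need >= 3 rows so a majority consensus exists outside the focal row")
  if (is.character(focal_platform))
    focal_platform <- match(focal_platform, rownames(mat))
  if (is.na(focal_platform)) stop("focal platform not found")
  f <- toupper(mat[focal_platform, ])
  others <- toupper(mat[-focal_platform, , drop = FALSE])
  counts <- stats::setNames(integer(5), c(BASES, "N"))
  ins_added <- 0L
  subs <- 0L
  for (col in seq_len(ncol(mat))) {
    oc <- others[, col]
    oc <- oc[oc != "N"]                       # Ns are uninformative votes
    if (length(oc) == 0L) next
    tab <- table(oc)
    top <- names(tab)[tab == max(tab)]
    fc <- f[col]
    if (fc %in% BASES && length(top) == 1L && top == "-") {
      n_gap <- sum(oc == "-")
      n_base <- sum(oc %in% BASES) + 1L       # focal row included
      if (n_base >= n_gap) ins_added <- ins_added + 1L
      else counts[fc] <- counts[fc] + 1L
    } else if (fc == "N" && all(top %in% BASES)) {
      counts["N"] <- counts["N"] + 1L
    } else if (fc %in% BASES && length(top) == 1L && top %in% BASES &&
               fc != top) {
      subs <- subs + 1L
    }
  }
  total_bp <- sum(f != "-")
  list(counts = counts, insertions_added = ins_added,
       substitutions = subs, total_bp = total_bp,
       rate_percent = phantom_rate(counts, total_bp))
}

#' Phantom-nucleotide rate
#'
#' Phantom calls (A, C, G, T and N rows) as a percentage of the total
#' reconstructed sequence, rounded half-up to two decimals. The
#' "insertions added" category is not part of the numerator.
#'
#' @param counts named numeric vector of phantom counts (any subset of
#'   A, C, G, T, N).
#' @param total_bp reconstructed sequence length (> 0).
#' @return percentage, 2 decimal places.
#' @examples
#' phantom_rate(c(A = 4, C = 1, T = 2, N = 8), 5406)   # 0.28
#' phantom_rate(c(A = 11, C = 5, G = 2, T = 12, N = 16), 10746)  # 0.43
#' @export
phantom_rate <- function(counts, total_bp) {
  if (!is.numeric(total_bp) || total_bp <= 0) stop("total_bp must be > 0")
  counts <- counts[names(counts) %in% c(BASES, "N")]
  round_half_up(100 * sum(counts) / total_bp, 2)
}

#' GC content of a sequence
#'
#' 100 x (G + C) / (A + C + G + T); gaps, N and ambiguity codes are excluded
#' from both numerator and denominator. Reported to one decimal place.
#'
#' @param seq character scalar (or [circular_genome()] / reconstruction).
#' @return percentage, 1 decimal place.
#' @export
gc_percent <- function(seq) {
  if (inherits(seq, "circular_genome") || inherits(seq, "reconstruction"))
    seq <- seq$seq
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n_gc <- sum(ch %in% c("G", "C"))
  n_acgt <- sum(ch %in% BASES)
  if (n_acgt == 0L) stop("sequence has no unambiguous bases")
  round_half_up(100 * n_gc / n_acgt, 1)
}
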