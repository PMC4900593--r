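#' Mapping parameter set
#'
#' Parameters of the k-mer-seeded read mapper used for windowed read
#' extraction and for iterative baited assembly.
#'
#' @param max_mismatch_frac maximum mismatch fraction per read (over aligned,
#'   non-gap positions).
#' @param max_gap_frac maximum total gapped fraction per read (0 disables
#'   gapped alignment).
#' @param max_gap_size maximum size of a single gap (bases).
#' @param word_length k-mer seed length.
#' @param max_ambiguity maximum number of ambiguous (non-ACGT) bases
#'   tolerated in a read.
#' @param iterations maximum assembly iterations.
#' @param multi_best placement policy when several placements tie:
#'   \code{"random"} (seeded) or \code{"first"}.
#' @param extend allow end-overhanging (clipped) placements and use their
#'   overhangs to extend the assembly; when FALSE reads must map entirely
#'   within the reference.
#' @param anchor_min minimum within-reference anchor (bases) for a clipped
#'   placement.
#' @export
map_params <- function(max_mismatch_frac = 0.03, max_gap_frac = 0.05,
                       max_gap_size = 15L, word_length = 14L,
                       max_ambiguity = 1L, iterations = 100L,
                       multi_best = c("random", "first"),
                       extend = TRUE, anchor_min = 30L) {
  multi_best <- match.arg(multi_best)
  stop_if_not_prob(max_mismatch_frac, "max_mismatch_frac")
  stop_if_not_prob(max_gap_frac, "max_gap_frac")
  if (iterations < 1L) stop("iterations must be >= 1")
  structure(list(max_mismatch_frac = max_mismatch_frac,
                 max_gap_frac = max_gap_frac,
                 max_gap_size = as.integer(max_gap_size),
                 word_length = as.integer(word_length),
                 max_ambiguity = as.integer(max_ambiguity),
                 iterations = as.integer(iterations),
                 multi_best = multi_best, extend = extend,
                 anchor_min = as.integer(anchor_min)),
            class = "map_params")
}

#' Named mapping presets
#'
#' \describe{
#'   \item{multiplex_initial}{first-pass baited assembly of pooled amplicon
#'     reads against heterospecific seeds: 3\% mismatches per read, maximum
#'     gap size 15, maximum ambiguity 1, multiple best matches placed
#'     randomly, 100 iterations.}
#'   \item{multiplex_rescue}{second pass against conspecific references to
#'     rescue reads while respecting intraspecific variation: 1\% mismatches,
#'     maximum ambiguity 2.}
#'   \item{hiseq_extract}{windowed extraction from a raw non-indexed pool:
#'     15\% gaps allowed per read, maximum gap size 50, word length 14,
#'     maximum ambiguity 4, single iteration; the mismatch threshold is
#'     supplied per window (see [compute_threshold()]).}
#' }
#'
#' @param name preset name.
#' @return a [map_params()] object.
#' @export
preset_map_params <- function(name = c("multiplex_initial",
                                       "multiplex_rescue",
                                       "hiseq_extract")) {
  switch(match.arg(name),
    multiplex_initial = map_params(max_mismatch_frac = 0.03,
                                   max_gap_size = 15L, max_ambiguity = 1L,
                                   iterations = 100L),
    multiplex_rescue = map_params(max_mismatch_frac = 0.01,
                                  max_gap_size = 15L, max_ambiguity = 2L,
                                  iterations = 100L),
    hiseq_extract = map_params(max_mismatch_frac = 0.45,
                               max_gap_frac = 0.15, max_gap_size = 50L,
                               word_length = 14L, max_ambiguity = 4L,
                               iterations = 1L))
}

## k-mer position index of a reference string.
kmer_index <- function(ref, k) {
  L <- nchar(ref)
  if (L < k) stop("reference shorter than word length")
  kmers <- substring(ref, 1:(L - k + 1L), k:L)
  idx <- split(seq_len(L - k + 1L), kmers)
  list(index = idx, keys = names(idx), k = k, L = L,
       raw = charToRaw(ref), ref = ref)
}

## Precompute the per-orientation k-mers of a read once; reads are mapped
## repeatedly against changing references during iterative assembly.
prep_read <- function(read, k, max_ambiguity) {
  qlen <- nchar(read)
  orient <- list()
  for (strand in c("+", "-")) {
    rseq <- if (strand == "+") read else revcomp(read)
    if (lengths(regmatches(rseq, gregexpr("[^ACGT]", rseq))) >
        max_ambiguity) next
    qk <- if (qlen >= k) substring(rseq, 1:(qlen - k + 1L), k:qlen)
          else character(0)
    orient[[strand]] <- list(seq = rseq, raw = charToRaw(rseq), qk = qk)
  }
  list(qlen = qlen, orient = orient)
}

## Candidate diagonals for one read orientation, by seed-vote count.
seed_diagonals <- function(qk, idx, max_candidates = 4L) {
  if (length(qk) == 0L) return(integer(0))
  m <- match(qk, idx$keys)
  found <- !is.na(m)
  if (!any(found)) return(integer(0))
  hits <- idx$index[m[found]]
  offs <- rep.int(which(found), lengths(hits))
  pos <- unlist(hits, use.names = FALSE)
  diag <- pos - offs + 1L
  ud <- unique(diag)
  votes <- tabulate(match(diag, ud))
  ud[order(-votes)][seq_len(min(max_candidates, length(ud)))]
}

## Ungapped evaluation of a read placed with its first base at reference
## position d (1-based; d may be outside [1, L] for clipped placements).
hamming_eval <- function(read_raw, qlen, d, idx) {
  a1 <- max(d, 1L); a2 <- min(d + qlen - 1L, idx$L)
  alen <- a2 - a1 + 1L
  if (alen <= 0L) return(NULL)
  mism <- sum(idx$raw[a1:a2] != read_raw[(a1 - d + 1L):(a2 - d + 1L)])
  list(start = d, anchor_start = a1, anchor_end = a2, anchor_len = alen,
       mismatches = as.integer(mism), mismatch_frac = mism / alen,
       score = alen - mism,
       clip_left = a1 - d, clip_right = (d + qlen - 1L) - a2)
}

## Gapped fallback: fit the whole read into a local window of the reference
## around diagonal d (Smith-Waterman via Biostrings, read global / subject
## local), honouring per-read gap constraints.
gapped_eval <- function(rseq, d, idx, params) {
  qlen <- nchar(rseq)
  pad <- params$max_gap_size + 10L
  w1 <- max(d - pad, 1L); w2 <- min(d + qlen - 1L + pad, idx$L)
  if (w2 - w1 + 1L < qlen * 0.5) return(NULL)
  win <- substr(idx$ref, w1, w2)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(rseq), Biostrings::DNAString(win),
    type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  gap_runs <- rle(pa == "-" | sa == "-")
  gap_w <- gap_runs$lengths[gap_runs$values]
  gap_total <- sum(gap_w)
  gap_max <- if (length(gap_w)) max(gap_w) else 0L
  both <- pa != "-" & sa != "-"
  aligned <- sum(both)
  mism <- sum(pa[both] != sa[both])
  if (aligned <= 0L) return(NULL)
  if (gap_total > params$max_gap_frac * qlen || gap_max > params$max_gap_size)
    return(NULL)
  sstart <- w1 + Biostrings::start(Biostrings::subject(al)) - 1L
  list(start = sstart, anchor_start = sstart,
       anchor_end = w1 + Biostrings::end(Biostrings::subject(al)) - 1L,
       anchor_len = aligned, mismatches = as.integer(mism),
       mismatch_frac = mism / aligned, score = aligned - mism,
       clip_left = 0L, clip_right = 0L, gapped = TRUE)
}

## Map one read (both strands) to an indexed reference. Returns NULL when no
## acceptable placement exists; otherwise the best placement with the
## oriented read sequence attached. `read` may be a string or a prepped
## read from prep_read().
map_read <- function(read, idx, params, mismatch_limit = NULL) {
  if (is.character(read))
    read <- prep_read(read, params$word_length, params$max_ambiguity)
  limit <- mismatch_limit %||% params$max_mismatch_frac
  qlen <- read$qlen
  best <- NULL
  for (strand in names(read$orient)) {
    o <- read$orient[[strand]]
    rseq <- o$seq
    rraw <- o$raw
    for (d in seed_diagonals(o$qk, idx)) {
      ev <- hamming_eval(rraw, qlen, d, idx)
      if (is.null(ev)) next
      clipped <- (ev$clip_left + ev$clip_right) > 0L
      if (clipped) {
        if (!params$extend) next
        ## a clipped read must sit at least half inside the reference (and
        ## never anchor on fewer than anchor_min bases): judging a read on a
        ## short terminal slice would let diverged reads through
        if (ev$anchor_len < min(max(params$anchor_min,
                                    ceiling(qlen / 2)), qlen)) next
      }
      ok <- ev$mismatch_frac <= limit
      if (!ok && params$max_gap_frac > 0 && !clipped) {
        g <- gapped_eval(rseq, d, idx, params)
        if (!is.null(g) && g$mismatch_frac <= limit) { ev <- g; ok <- TRUE }
      }
      if (!ok) next
      ev$strand <- strand; ev$oriented <- rseq; ev$qlen <- qlen
      if (is.null(best) || ev$score > best$score ||
          (ev$score == best$score && params$multi_best == "random" &&
           stats::runif(1) < 0.5))
        best <- ev
    }
  }
  best
}

#' Extract taxon-relevant reads from a pooled read set
#'
#' Retains a read iff its best seeded placement against the window consensus
#' (either strand; gapped fallback within the preset's gap constraints) has
#' a mismatch fraction at or below the window threshold. This is the
#' per-window read-binning step used to distil a non-indexed multiplex pool
#' down to the taxa of interest.
#'
#' @param pool a \code{read_set} (see [simulate_reads()]) or data.frame with
#'   \code{read_id}, \code{seq}.
#' @param consensus window consensus sequence (gap-free).
#' @param threshold per-read mismatch fraction threshold in [0, 1]
#'   (see [compute_threshold()]).
#' @param params a [map_params()]; default the windowed-extraction preset.
#' @param seed RNG seed (tie-breaking).
#' @return The retained subset of \code{pool} (same class), with an
#'   attribute \code{"stats"} (n_input, n_retained) and per-read mapping
#'   details in attribute \code{"hits"}.
#' @export
extract_reads <- function(pool, consensus, threshold,
                          params = preset_map_params("hiseq_extract"),
                          seed = NULL) {
  stop_if_not_prob(threshold, "threshold")
  if (nchar(consensus) < params$word_length)
    stop("consensus shorter than the seed word length")
  reads <- if (inherits(pool, "read_set")) pool$reads else pool
  if (nrow(reads) == 0L) {
    out <- pool
    if (inherits(pool, "read_set")) {
      out$reads <- reads; out$truth <- pool$truth[0, ]
    }
    attr(out, "stats") <- c(n_input = 0L, n_retained = 0L)
    return(out)
  }
  idx <- kmer_index(consensus, params$word_length)
  with_seed(seed, {
    hits <- lapply(reads$seq, map_read, idx = idx, params = params,
                   mismatch_limit = threshold)
    keep <- !vapply(hits, is.null, logical(1))
    out <- pool
    if (inherits(pool, "read_set")) {
      out$reads <- reads[keep, , drop = FALSE]
      out$truth <- pool$truth[pool$truth$read_id %in% out$reads$read_id, ,
                              drop = FALSE]
    } else out <- reads[keep, , drop = FALSE]
    attr(out, "stats") <- c(n_input = nrow(reads),
                            n_retained = sum(keep))
    attr(out, "hits") <- hits[keep]
    out
  })
}
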