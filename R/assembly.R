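## byte -> base index lookup (A,C,G,T = 1..4; anything else 0)
BASE_IDX <- local({
  m <- integer(256)
  m[utf8ToInt("A") + 1L] <- 1L
  m[utf8ToInt("C") + 1L] <- 2L
  m[utf8ToInt("G") + 1L] <- 3L
  m[utf8ToInt("T") + 1L] <- 4L
  m
})

reconstruction <- function(specimen, platform, seq, coverage, reads_used,
                           complete, iterations_run = NA_integer_,
                           warning_flag = NULL) {
  stopifnot(nchar(seq) == length(coverage))
  structure(list(specimen = specimen, platform = platform, seq = seq,
                 coverage = coverage, reads_used = reads_used,
                 complete = complete, iterations_run = iterations_run,
                 warning_flag = warning_flag),
            class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf(
    "<reconstruction> %s [%s]: %d bp, mean coverage %.1fx, %s\n",
    x$specimen, x$platform %||% "?", nchar(x$seq), mean(x$coverage),
    if (isTRUE(x$complete)) "complete" else "incomplete"))
  invisible(x)
}

## read sequences out of whatever container the caller holds
read_seqs_of <- function(reads) {
  if (inherits(reads, "read_set")) reads$reads$seq
  else if (is.data.frame(reads)) reads$seq
  else as.character(reads)
}

#' Iterative reference-baited assembly
#'
#' Maps reads to the current reference with a k-mer-seeded mapper, replaces
#' the reference by the per-column majority of the mapped read bases, and —
#' when extension is enabled — grows the reference at both ends with the
#' consensus of overhanging read bases (at most half a read length per end
#' per iteration, which keeps runaway chimeric extension in check), until
#' nothing changes or the iteration cap is reached. Positions never covered
#' by a read are reported as N. When the reference is a linearised circular
#' genome and extension is off, reads spanning the circle's origin cannot be
#' placed, so coverage decays to zero at the reference ends — the edge
#' artifact the reference-rotation protocol (see [assemble_with_rotation()])
#' exists to repair.
#'
#' @param reads a \code{read_set}, data.frame with \code{seq}, or character
#'   vector of read sequences.
#' @param seed_ref starting reference sequence (bait).
#' @param params a [map_params()]; \code{params$extend} controls clipped
#'   placements and end extension.
#' @param seed RNG seed (random placement of tied matches).
#' @param specimen,platform labels carried into the result.
#' @return A \code{reconstruction}: \code{seq} (may contain N and IUPAC
#'   ambiguity at consensus ties), per-base \code{coverage},
#'   \code{reads_used}, \code{complete} flag, \code{iterations_run}.
#' @export
iterative_bait_assemble <- function(reads, seed_ref,
                                    params = preset_map_params(
                                      "multiplex_initial"),
                                    seed = NULL, specimen = "specimen",
                                    platform = NA_character_) {
  seqs <- read_seqs_of(reads)
  if (!is.character(seed_ref) || nchar(seed_ref) < params$word_length)
    stop("seed_ref must be a sequence at least one seed word long")
  working <- toupper(seed_ref)
  if (length(seqs) == 0L)
    return(reconstruction(specimen, platform, working,
                          rep(0L, nchar(working)), 0L, FALSE, 0L))
  mean_qlen <- mean(nchar(seqs))
  ext_cap <- max(1L, floor(mean_qlen / 2))
  prepped <- lapply(seqs, prep_read, k = params$word_length,
                    max_ambiguity = params$max_ambiguity)

  with_seed(seed, {
    counts <- NULL; n_mapped <- 0L; it_done <- 0L
    for (it in seq_len(params$iterations)) {
      it_done <- it
      L <- nchar(working)
      idx <- kmer_index(working, params$word_length)
      hits <- lapply(prepped, map_read, idx = idx, params = params)
      mapped <- !vapply(hits, is.null, logical(1))
      n_mapped <- sum(mapped)
      if (n_mapped == 0L)
        return(reconstruction(specimen, platform, toupper(seed_ref),
                              rep(0L, nchar(seed_ref)), 0L, FALSE, it))
      ## per-column base counts from anchored placements
      pos_all <- vector("list", n_mapped)
      base_all <- vector("list", n_mapped)
      left_ov <- list(); right_ov <- list()
      mi <- 0L
      for (h in hits[mapped]) {
        mi <- mi + 1L
        rr <- BASE_IDX[as.integer(charToRaw(h$oriented)) + 1L]
        off <- (h$anchor_start - h$start + 1L):(h$anchor_end - h$start + 1L)
        pos_all[[mi]] <- h$anchor_start:h$anchor_end
        base_all[[mi]] <- rr[off]
        if (isTRUE(params$extend)) {
          if (h$clip_left > 0L)
            left_ov[[length(left_ov) + 1L]] <-
              list(dist = h$clip_left:1L, base = rr[1:h$clip_left])
          if (h$clip_right > 0L)
            right_ov[[length(right_ov) + 1L]] <-
              list(dist = 1L:h$clip_right,
                   base = rr[(h$qlen - h$clip_right + 1L):h$qlen])
        }
      }
      pos <- unlist(pos_all); base <- unlist(base_all)
      keepb <- base > 0L
      counts <- matrix(tabulate(pos[keepb] + L * (base[keepb] - 1L),
                                nbins = 4L * L), nrow = L)
      cov <- rowSums(counts)
      maj <- max.col(counts, ties.method = "first")
      new_working <- ifelse(cov > 0L, BASES[maj],
                            strsplit(working, "", fixed = TRUE)[[1]])
      ## end extension from overhang consensus
      ext_l <- ext_r <- ""
      if (isTRUE(params$extend)) {
        ext_l <- overhang_consensus(left_ov, ext_cap, reverse = TRUE)
        ext_r <- overhang_consensus(right_ov, ext_cap, reverse = FALSE)
      }
      candidate <- paste0(ext_l, paste(new_working, collapse = ""), ext_r)
      if (candidate == working) break
      working <- candidate
    }
    ## final call: majority with IUPAC ties, N where never covered
    L <- nchar(working)
    if (is.null(counts) || nrow(counts) != L) {
      idx <- kmer_index(working, params$word_length)
      hits <- lapply(prepped, map_read, idx = idx, params = params)
      mapped <- !vapply(hits, is.null, logical(1))
      n_mapped <- sum(mapped)
      pos <- integer(0); base <- integer(0)
      for (h in hits[mapped]) {
        rr <- BASE_IDX[as.integer(charToRaw(h$oriented)) + 1L]
        off <- (h$anchor_start - h$start + 1L):(h$anchor_end - h$start + 1L)
        pos <- c(pos, h$anchor_start:h$anchor_end)
        base <- c(base, rr[off])
      }
      keepb <- base > 0L
      counts <- matrix(tabulate(pos[keepb] + L * (base[keepb] - 1L),
                                nbins = 4L * L), nrow = L)
    }
    cov <- as.integer(rowSums(counts))
    out <- character(L)
    for (p in seq_len(L)) {
      if (cov[p] == 0L) { out[p] <- "N"; next }
      top <- BASES[counts[p, ] == max(counts[p, ])]
      out[p] <- iupac_code(top)
    }
    reconstruction(specimen, platform, paste(out, collapse = ""), cov,
                   n_mapped, complete = !any(out == "N"), it_done)
  })
}

## consensus string of end overhangs; positions with no support stop the
## extension. `dist` is distance beyond the reference end (1 = adjacent).
overhang_consensus <- function(ovs, cap, reverse) {
  if (length(ovs) == 0L) return("")
  dist <- unlist(lapply(ovs, `[[`, "dist"))
  base <- unlist(lapply(ovs, `[[`, "base"))
  ok <- base > 0L & dist <= cap
  if (!any(ok)) return("")
  dist <- dist[ok]; base <- base[ok]
  maxd <- max(dist)
  cnt <- matrix(tabulate(dist + maxd * (base - 1L), nbins = 4L * maxd),
                nrow = maxd)
  covd <- rowSums(cnt)
  reach <- which(covd == 0L)
  maxd <- if (length(reach)) min(reach) - 1L else maxd
  if (maxd < 1L) return("")
  chars <- BASES[max.col(cnt[seq_len(maxd), , drop = FALSE],
                         ties.method = "first")]
  if (reverse) paste(rev(chars), collapse = "")
  else paste(chars, collapse = "")
}

#' Assemble with the reference-rotation protocol
#'
#' Runs [iterative_bait_assemble()] twice — once on the reference as given
#' and once with its last \code{rotate_k} bases moved to the front — then
#' derotates the second run back to the first run's coordinates and merges
#' the two by per-position majority (N yields to a called base; conflicting
#' calls are settled by coverage, ties becoming IUPAC ambiguities), with
#' coverage combined as the per-base maximum. Because each run's unrecovered
#' terminal segment sits in the other run's interior, the merge recovers the
#' complete circle. Both runs are reference-bounded (no end extension): the
#' protocol exists for full-length circular references, where the edge
#' artifact, not reference growth, is the problem.
#'
#' @inheritParams iterative_bait_assemble
#' @param rotate_k rotation amount in bases (must be < reference length).
#' @return A \code{reconstruction}; if the two runs share fewer than
#'   \code{2 * rotate_k} agreeing bases the longer run is returned with
#'   \code{warning_flag} set.
#' @export
assemble_with_rotation <- function(reads, seed_ref,
                                   params = preset_map_params(
                                     "multiplex_initial"),
                                   rotate_k = 1000L, seed = NULL,
                                   specimen = "specimen",
                                   platform = NA_character_) {
  if (rotate_k >= nchar(seed_ref))
    stop("rotate_k must be smaller than the reference length")
  params$extend <- FALSE
  r1 <- iterative_bait_assemble(reads, seed_ref, params, seed = seed,
                                specimen = specimen, platform = platform)
  r2 <- iterative_bait_assemble(reads, rotate_reference(seed_ref, rotate_k),
                                params, seed = seed, specimen = specimen,
                                platform = platform)
  L1 <- nchar(r1$seq); L2 <- nchar(r2$seq)
  ## derotate run 2 into run 1's frame
  s2 <- rotate_reference(r2$seq, L2 - rotate_k)
  c2 <- rotate_vec(r2$coverage, L2 - rotate_k)

  if (L1 == L2) {
    a <- strsplit(r1$seq, "", fixed = TRUE)[[1]]
    b <- strsplit(s2, "", fixed = TRUE)[[1]]
    agree <- sum(a == b & a != "N")
    if (agree < 2 * rotate_k) {
      best <- if (L1 >= L2) r1 else r2
      best$warning_flag <- "rotated runs share too little aligned sequence"
      return(best)
    }
    ca <- r1$coverage; cb <- c2
    out <- ifelse(a == b, a,
           ifelse(a == "N", b,
           ifelse(b == "N", a,
           ifelse(ca > cb, a,
           ifelse(cb > ca, b,
                  mapply(function(x, y) iupac_code(c(x, y)), a, b))))))
    cov <- pmax(ca, cb)
    return(reconstruction(specimen, platform, paste(out, collapse = ""),
                          as.integer(cov),
                          max(r1$reads_used, r2$reads_used),
                          complete = !any(out == "N") && all(cov > 0),
                          max(r1$iterations_run, r2$iterations_run)))
  }
  ## unequal lengths: align the two runs and take a trimmed majority,
  ## dropping columns where either run has an end gap
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(gsub("[^ACGT]", "N", r1$seq)),
    Biostrings::DNAString(gsub("[^ACGT]", "N", s2)),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  agree <- sum(pa == sa & pa != "N" & pa != "-")
  if (agree < 2 * rotate_k) {
    best <- if (L1 >= L2) r1 else r2
    best$warning_flag <- "rotated runs share too little aligned sequence"
    return(best)
  }
  keep <- !(pa == "-" | sa == "-")
  out <- ifelse(pa[keep] == sa[keep], pa[keep],
         ifelse(pa[keep] == "N", sa[keep],
         ifelse(sa[keep] == "N", pa[keep],
                mapply(function(x, y) iupac_code(c(x, y)),
                       pa[keep], sa[keep]))))
  cov <- rep(1L, sum(keep))
  reconstruction(specimen, platform, paste(out, collapse = ""), cov,
                 max(r1$reads_used, r2$reads_used),
                 complete = !any(out == "N"),
                 max(r1$iterations_run, r2$iterations_run))
}

rotate_vec <- function(v, k) {
  n <- length(v)
  k <- k %% n
  if (k == 0L) return(v)
  c(v[(n - k + 1L):n], v[seq_len(n - k)])
}

#' Coverage report for a reconstruction
#'
#' Summarises a run the way platform-comparison coverage tables do: number
#' of reads used and the approximate number of sequenced bases they
#' represent (reads x mean read length), plus the mean per-base coverage
#' and reconstructed length.
#'
#' @param recon a \code{reconstruction}, or NULL to report arithmetic only.
#' @param reads_used read count (defaults to the reconstruction's).
#' @param mean_read_len platform mean read length (bp).
#' @return list: \code{reads}, \code{approx_bp}, \code{mean_cov},
#'   \code{length}.
#' @export
coverage_report <- function(recon = NULL, reads_used = recon$reads_used,
                            mean_read_len) {
  approx_bp <- as.numeric(reads_used) * mean_read_len
  list(reads = reads_used,
       approx_bp = approx_bp,
       mean_cov = if (!is.null(recon)) mean(recon$coverage) else NA_real_,
       length = if (!is.null(recon)) nchar(recon$seq) else NA_integer_)
}
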