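#' Sequencing platform profile
#'
#' Encodes the read-length and error behaviour of a sequencing platform.
#' The named presets carry the mean read lengths observed for each platform
#' in a multi-platform mitogenome comparison (MiSeq 448 bp, HiSeq 95 bp,
#' 454 523 bp, Ion Torrent 98 bp); error rates are free parameters with
#' documented defaults (substitutions 0.2\%, homopolymer indels 0 for the
#' Illumina chemistries and 0.5\% per homopolymer run for the
#' pyro/semiconductor chemistries, which are prone to homopolymer
#' length-call errors).
#'
#' @param name one of \code{"miseq"}, \code{"hiseq"}, \code{"r454"},
#'   \code{"iontorrent"}, \code{"custom"}.
#' @param mean_read_len,read_len_sd read length distribution (bp).
#' @param paired emit mate pairs?
#' @param insert_mean,insert_sd fragment length for paired profiles (bp).
#' @param sub_error_rate per-base substitution error probability.
#' @param homopolymer_indel_rate per-homopolymer-run (length >= 3)
#'   probability of a one-base length error.
#' @param yield_reads default number of reads (fragments) to simulate.
#' @export
platform_profile <- function(name = c("custom", "miseq", "hiseq", "r454",
                                      "iontorrent"),
                             mean_read_len = NULL, read_len_sd = NULL,
                             paired = NULL, insert_mean = NULL,
                             insert_sd = 40,
                             sub_error_rate = NULL,
                             homopolymer_indel_rate = NULL,
                             yield_reads = 1000L) {
  name <- match.arg(name)
  defaults <- list(
    miseq      = list(len = 448, sd = 50, paired = FALSE, sub = 0.002, hp = 0),
    hiseq      = list(len = 95,  sd = 8,  paired = TRUE,  sub = 0.002, hp = 0),
    r454       = list(len = 523, sd = 80, paired = FALSE, sub = 0.002,
                      hp = 0.005),
    iontorrent = list(len = 98,  sd = 12, paired = FALSE, sub = 0.002,
                      hp = 0.005),
    custom     = list(len = 100, sd = 10, paired = FALSE, sub = 0, hp = 0))
  d <- defaults[[name]]
  p <- structure(list(
    name = name,
    mean_read_len = mean_read_len %||% d$len,
    read_len_sd = read_len_sd %||% d$sd,
    paired = paired %||% d$paired,
    insert_mean = insert_mean %||% (3 * (mean_read_len %||% d$len)),
    insert_sd = insert_sd,
    sub_error_rate = sub_error_rate %||% d$sub,
    homopolymer_indel_rate = homopolymer_indel_rate %||% d$hp,
    yield_reads = as.integer(yield_reads)), class = "platform_profile")
  if (p$mean_read_len <= 0) stop("mean_read_len must be > 0")
  stop_if_not_prob(p$sub_error_rate, "sub_error_rate")
  stop_if_not_prob(p$homopolymer_indel_rate, "homopolymer_indel_rate")
  p
}

## Apply per-base substitution errors to a vector of reads.
apply_sub_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(ch)) < rate)
    for (i in hit) ch[i] <- sample(setdiff(BASES, ch[i]), 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## One-base homopolymer length errors: each run of length >= 3 gains or
## loses one base with probability `rate`.
apply_homopolymer_indels <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
    runs <- which(r$lengths >= 3L)
    hit <- runs[stats::runif(length(runs)) < rate]
    for (i in hit) r$lengths[i] <- r$lengths[i] +
        if (stats::runif(1) < 0.5) 1L else -1L
    paste(rep.int(r$values, r$lengths), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## Internal read-set constructor: reads + truth labels kept side by side.
read_set <- function(reads, truth, platform) {
  structure(list(reads = reads, truth = truth, platform = platform),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads (%s), %d truth labels\n",
              nrow(x$reads), x$platform, nrow(x$truth)))
  invisible(x)
}

#' Simulate a platform read set from a circular genome
#'
#' Reads are drawn from circular coordinates (they may span the origin, in
#' which case they are emitted as contiguous strings from the doubled
#' genome), given platform-profile errors, and each carries a truth label
#' recording its source interval so that extraction and assembly accuracy
#' can be scored exactly.
#'
#' @param genome a [circular_genome()] (or a plain sequence string).
#' @param profile a [platform_profile()].
#' @param seed RNG seed or NULL.
#' @param yield_reads number of fragments; defaults to the profile's.
#' @param circular draw fragments across the origin (TRUE) or only from the
#'   linear span (FALSE, used for amplicon fragments).
#' @return A \code{read_set}: \code{$reads} is a data.frame
#'   (read_id, seq, platform), \code{$truth} a data.frame
#'   (read_id, source_taxon, start, end, strand) with 0-based half-open
#'   wrapped intervals.
#' @export
simulate_reads <- function(genome, profile, seed = NULL,
                           yield_reads = profile$yield_reads,
                           circular = TRUE) {
  if (is.character(genome)) genome <- circular_genome("genome", genome)
  stopifnot(inherits(genome, "circular_genome"),
            inherits(profile, "platform_profile"))
  n <- as.integer(yield_reads)
  if (n == 0L) {
    empty <- data.frame(read_id = character(), seq = character(),
                        platform = character(), stringsAsFactors = FALSE)
    truth <- data.frame(read_id = character(), source_taxon = character(),
                        start = integer(), end = integer(),
                        strand = character(), stringsAsFactors = FALSE)
    return(read_set(empty, truth, profile$name))
  }
  L <- genome$length
  with_seed(seed, {
    frag_len_for <- function(target) {
      len <- round(stats::rnorm(n, target, profile$read_len_sd))
      pmin(pmax(len, 30L), L)
    }
    if (profile$paired) {
      flen <- pmin(pmax(round(stats::rnorm(n, profile$insert_mean,
                                           profile$insert_sd)), 60L), L)
      rlen <- frag_len_for(profile$mean_read_len)
      rlen <- pmin(rlen, flen)
    } else {
      flen <- rlen <- frag_len_for(profile$mean_read_len)
    }
    start <- if (circular) sample.int(L, n, replace = TRUE) - 1L
             else vapply(flen, function(fl)
               sample.int(max(L - fl + 1L, 1L), 1L) - 1L, integer(1))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    frag <- vapply(seq_len(n), function(i)
      circular_substring(genome$seq, start[i], flen[i]), character(1))

    if (profile$paired) {
      ids <- sprintf("%s_%s_%06d", genome$id, profile$name, seq_len(n))
      neg <- strand == "-"
      oriented <- frag
      oriented[neg] <- revcomp_many(frag[neg])
      m1 <- substr(oriented, 1L, rlen)
      m2 <- revcomp_many(substring(oriented, pmax(flen - rlen + 1L, 1L), flen))
      seqs <- c(m1, m2)
      read_id <- c(paste0(ids, "/1"), paste0(ids, "/2"))
      ## per-mate source intervals on the circle; a "-" fragment swaps which
      ## end of the genomic interval each mate covers
      head_s <- start; head_e <- (start + rlen) %% L
      tail_s <- (start + flen - rlen) %% L; tail_e <- (start + flen) %% L
      s1 <- ifelse(neg, tail_s, head_s); e1 <- ifelse(neg, tail_e, head_e)
      s2 <- ifelse(neg, head_s, tail_s); e2 <- ifelse(neg, head_e, tail_e)
      starts <- c(s1, s2); ends <- c(e1, e2)
      strands <- c(strand, chartr("+-", "-+", strand))
    } else {
      seqs <- frag
      neg <- strand == "-"
      seqs[neg] <- revcomp_many(seqs[neg])
      read_id <- sprintf("%s_%s_%06d", genome$id, profile$name, seq_len(n))
      starts <- start; ends <- (start + flen) %% L
      strands <- strand
    }
    seqs <- apply_sub_errors(seqs, profile$sub_error_rate)
    seqs <- apply_homopolymer_indels(seqs, profile$homopolymer_indel_rate)

    reads <- data.frame(read_id = read_id, seq = seqs,
                        platform = profile$name, stringsAsFactors = FALSE)
    truth <- data.frame(read_id = read_id, source_taxon = genome$id,
                        start = as.integer(starts), end = as.integer(ends),
                        strand = strands, stringsAsFactors = FALSE)
    read_set(reads, truth, profile$name)
  })
}

## Concatenate read sets (shared platform label kept if unique).
combine_read_sets <- function(sets) {
  reads <- do.call(rbind, lapply(sets, `[[`, "reads"))
  truth <- do.call(rbind, lapply(sets, `[[`, "truth"))
  plat <- unique(vapply(sets, `[[`, character(1), "platform"))
  read_set(reads, truth, if (length(plat) == 1L) plat else "mixed")
}
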