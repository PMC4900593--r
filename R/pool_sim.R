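#' Two-fragment long-range amplicon scheme
#'
#' Describes, per taxon, the circular intervals of the long-range PCR
#' amplicons that were pooled for non-indexed multiplex sequencing. The
#' default mirrors a typical mitogenome design: two overlapping fragments of
#' roughly 6.4 kb and 10.7 kb whose union covers the circle, with a small
#' overlap at both junctions. Individual amplicons may be flagged as failed
#' (a real failure mode: a taxon then contributes only ~one third of its
#' genome to the pool).
#'
#' @param genomes named list of [circular_genome()].
#' @param frac1 fraction of the circle covered by the first fragment.
#' @param overlap overlap between the fragments at each junction (bp).
#' @param failed character vector of "taxon:amplicon" flags, e.g.
#'   \code{"G_larvata:2"}.
#' @return data.frame (taxon, amplicon, start, end, failed) with 0-based
#'   half-open wrapped intervals.
#' @export
amplicon_scheme <- function(genomes, frac1 = 0.39, overlap = 150,
                            failed = character()) {
  rows <- lapply(names(genomes), function(tx) {
    L <- genomes[[tx]]$length
    cut1 <- round(frac1 * L)
    data.frame(taxon = tx, amplicon = c(1L, 2L),
               start = c(0L, (cut1 - overlap) %% L),
               end = c(cut1, overlap %% L),
               failed = paste(tx, c(1L, 2L), sep = ":") %in% failed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a non-indexed pooled amplicon read set
#'
#' Generates reads from each taxon's non-failed amplicons under a shared or
#' per-taxon platform profile and pools them with anonymised read ids (no
#' index information), keeping truth labels separately. If the non-failed
#' amplicons of a taxon do not cover its genome a warning is raised, not an
#' error (partial representation in the pool is a real outcome).
#'
#' @param genomes named list of [circular_genome()].
#' @param profiles a [platform_profile()] or named list of them (per taxon).
#' @param scheme an [amplicon_scheme()] data.frame.
#' @param reads_per_amplicon integer (recycled) or named numeric vector by
#'   taxon; reads simulated from each non-failed amplicon.
#' @param seed RNG seed.
#' @return A pooled \code{read_set}; \code{$truth$source_taxon} carries the
#'   per-read origin that the pooled ids deliberately hide.
#' @export
simulate_pool <- function(genomes, profiles, scheme = amplicon_scheme(genomes),
                          reads_per_amplicon = 200L, seed = NULL) {
  stopifnot(is.list(genomes), length(genomes) >= 1L)
  get_profile <- function(tx) {
    if (inherits(profiles, "platform_profile")) profiles
    else profiles[[tx]] %||% stop("no profile for taxon ", tx)
  }
  get_n <- function(tx) {
    if (length(reads_per_amplicon) == 1L && is.null(names(reads_per_amplicon)))
      reads_per_amplicon
    else reads_per_amplicon[[tx]] %||% stop("no read count for taxon ", tx)
  }
  with_seed(seed, {
    sets <- list()
    for (tx in names(genomes)) {
      g <- genomes[[tx]]
      amps <- scheme[scheme$taxon == tx & !scheme$failed, , drop = FALSE]
      if (nrow(amps) == 0L) next
      lens <- circ_interval_length(amps$start, amps$end, g$length)
      if (sum(lens) < g$length)
        warning("amplicons for taxon ", tx, " do not cover its genome",
                call. = FALSE)
      for (a in seq_len(nrow(amps))) {
        alen <- lens[a]
        frag <- circular_substring(g$seq, amps$start[a], alen)
        sub <- circular_genome(tx, frag)
        rs <- simulate_reads(sub, get_profile(tx), yield_reads = get_n(tx),
                             circular = FALSE)
        ## map truth intervals from amplicon to genome coordinates
        rs$truth$start <- (rs$truth$start + amps$start[a]) %% g$length
        rs$truth$end <- (rs$truth$end + amps$start[a]) %% g$length
        ## ids must be unique across amplicons before pooling
        rs$reads$read_id <- sprintf("%s.amp%d.%s", tx, amps$amplicon[a],
                                    rs$reads$read_id)
        rs$truth$read_id <- sprintf("%s.amp%d.%s", tx, amps$amplicon[a],
                                    rs$truth$read_id)
        sets[[length(sets) + 1L]] <- rs
      }
    }
    if (length(sets) == 0L)
      return(simulate_reads(genomes[[1]],
                            get_profile(names(genomes)[1]), yield_reads = 0L))
    pool <- combine_read_sets(sets)
    ## anonymise: a pooled, non-indexed run carries no sample information
    anon <- sprintf("pool_%06d", seq_len(nrow(pool$reads)))
    pool$truth$read_id <- anon[match(pool$truth$read_id, pool$reads$read_id)]
    pool$reads$read_id <- anon
    pool
  })
}
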