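#' Read/write sequence and tree files
#'
#' Thin wrappers over Biostrings and ape for the formats the pipeline
#' exchanges: FASTA for genomes/alignments/consensus references, FASTQ for
#' reads (Sanger Phred+33, constant quality on output), newick (one tree
#' per line) or a Nexus trees block for tree samples, and TSV for window
#' tables and truth labels.
#'
#' @param path file path.
#' @name mitopool-io
NULL

#' @rdname mitopool-io
#' @return \code{read_fasta}: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname mitopool-io
#' @param seqs named character vector, list of [circular_genome()]s or
#'   \code{reconstruction}s, or an alignment matrix.
#' @export
write_fasta <- function(seqs, path) {
  if (is.matrix(seqs))
    seqs <- stats::setNames(apply(seqs, 1, paste, collapse = ""),
                            rownames(seqs))
  if (is.list(seqs))
    seqs <- vapply(seqs, function(s)
      if (is.list(s)) s$seq else as.character(s), character(1))
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' @rdname mitopool-io
#' @param rs a \code{read_set} (see [simulate_reads()]) or data.frame with
#'   \code{read_id}, \code{seq}.
#' @export
write_fastq <- function(rs, path) {
  reads <- if (inherits(rs, "read_set")) rs$reads else rs
  x <- Biostrings::DNAStringSet(gsub("[^ACGT]", "N", reads$seq))
  names(x) <- reads$read_id
  q <- Biostrings::BStringSet(vapply(nchar(reads$seq), function(n)
    strrep("I", n), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname mitopool-io
#' @param platform platform label to attach to the reads.
#' @export
read_fastq <- function(path, platform = "unknown") {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  reads <- data.frame(read_id = names(x), seq = as.character(x),
                      platform = platform, stringsAsFactors = FALSE)
  truth <- data.frame(read_id = character(), source_taxon = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  read_set(reads, truth, platform)
}

#' @rdname mitopool-io
#' @param format \code{"newick"} (one tree per line) or \code{"nexus"}
#'   (trees block, translate table honoured).
#' @param source analysis label for the sample.
#' @export
read_tree_sample <- function(path, format = c("newick", "nexus"),
                             source = basename(path)) {
  format <- match.arg(format)
  trees <- switch(format,
                  newick = ape::read.tree(path),
                  nexus = ape::read.nexus(path))
  if (inherits(trees, "phylo")) trees <- list(trees)
  tree_sample(trees, source)
}

#' @rdname mitopool-io
#' @param sample a [tree_sample()].
#' @export
write_tree_sample <- function(sample, path) {
  ape::write.tree(sample$trees, path)
  invisible(path)
}

#' @rdname mitopool-io
#' @param df a data.frame (window table, truth labels, support table...).
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname mitopool-io
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
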