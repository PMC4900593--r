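## Shared fixture builders. Everything is generated in code, no files.

random_seq <- function(n, seed = NULL, freqs = rep(0.25, 4)) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freqs),
        collapse = "")
}

## error-free custom profile
clean_profile <- function(len = 95, sd = 8) {
  platform_profile("custom", mean_read_len = len, read_len_sd = sd,
                   sub_error_rate = 0, homopolymer_indel_rate = 0)
}

## two-taxon genome pair at a controlled divergence (no indels)
genome_pair <- function(len, bl, seed) {
  simulate_genomes(
    evolution_spec(sprintf("(X:%f,Y:%f);", bl / 2, bl / 2), seed = seed),
    len)
}

## the printed 16-window reduction table fixture
windows_fixture <- function() {
  read_tsv(system.file("extdata", "hiseq_reduction_windows.tsv",
                       package = "mitopool"))
}

phantom_fixture <- function() {
  read_tsv(system.file("extdata", "phantom_counts.tsv",
                       package = "mitopool"))
}

phantom_fixture_counts <- function(col) {
  pc <- phantom_fixture()
  stats::setNames(pc[[col]][match(c("A", "C", "G", "T", "N"), pc$row)],
                  c("A", "C", "G", "T", "N"))
}

phantom_fixture_total <- function(col) {
  pc <- phantom_fixture()
  pc[[col]][pc$row == "total_bp"]
}
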