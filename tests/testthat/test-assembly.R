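test_that("empty read sets return the seed unchanged and incomplete", {
  r <- iterative_bait_assemble(character(0), random_seq(300, seed = 1))
  expect_false(r$complete)
  expect_equal(r$reads_used, 0)
  expect_equal(nchar(r$seq), 300)
})

test_that("a seed window grows to cover the full circle on clean reads", {
  g <- simulate_genomes(evolution_spec("(X:0.01,Y:0.01);", seed = 33), 3000)
  truth <- g$genomes$X
  reads <- simulate_reads(truth, clean_profile(95, 8), seed = 9,
                          yield_reads = round(20 * 3000 / 95))
  seedref <- substr(truth$seq, 1001, 1400)
  p <- preset_map_params("multiplex_initial")
  p$iterations <- 200L
  r <- iterative_bait_assemble(reads, seedref, p, seed = 4)
  expect_gte(nchar(r$seq), truth$length)
  expect_false(grepl("N", r$seq, fixed = TRUE))
  ## assembled sequence is a faithful walk around the circle (no chimeras)
  expect_true(grepl(r$seq, strrep(truth$seq, 3), fixed = TRUE))
  ## coverage conservation: coverage sums to the aligned bases of the reads
  expect_lte(sum(r$coverage), sum(nchar(reads$reads$seq)))
  expect_gte(mean(r$coverage), 10)
})

test_that("full-reference runs show the linearisation edge artifact and the
           rotation protocol repairs it", {
  g <- simulate_genomes(evolution_spec("(X:0.003,Y:0.003);", seed = 21),
                        6000)
  truth <- g$genomes$X
  refseq <- g$genomes$Y$seq   # conspecific-level reference
  reads <- simulate_reads(truth, clean_profile(95, 8), seed = 5,
                          yield_reads = round(20 * 6000 / 95))
  p <- preset_map_params("multiplex_initial")
  p$extend <- FALSE
  single <- iterative_bait_assemble(reads, refseq, p, seed = 1)
  expect_false(single$complete)
  npos <- which(strsplit(single$seq, "")[[1]] == "N")
  expect_gt(length(npos), 0)
  ## the unrecovered segment sits at the reference ends
  expect_true(all(npos <= 150 | npos >= 6000 - 150))
  ## origin-spanning reads are the ones that could not be placed
  expect_lt(single$reads_used, nrow(reads$reads))

  merged <- assemble_with_rotation(reads, refseq, p, rotate_k = 1000,
                                   seed = 1)
  expect_true(merged$complete)
  expect_identical(merged$seq, truth$seq)
  expect_true(all(merged$coverage >= pmax(single$coverage, 0)))
})

test_that("tightening the mismatch limit never maps more reads", {
  g <- genome_pair(2000, 0.02, seed = 91)
  reads <- simulate_reads(g$genomes$X, clean_profile(90, 8), seed = 92,
                          yield_reads = 150)
  used <- vapply(c(0.05, 0.02, 0.01, 0.005), function(mm) {
    p <- map_params(max_mismatch_frac = mm, iterations = 1L, extend = FALSE)
    iterative_bait_assemble(reads, g$genomes$Y$seq, p, seed = 3)$reads_used
  }, numeric(1))
  expect_true(all(diff(used) <= 0))
})

test_that("rotation merging resolves N against the other run's call", {
  ## synthetic two-run merge exercised through the public interface:
  ## identical reads, rotation by a quarter of the circle
  g <- circular_genome("c", random_seq(1200, seed = 95))
  reads <- simulate_reads(g, clean_profile(80, 5), seed = 96,
                          yield_reads = 300)
  p <- preset_map_params("multiplex_initial")
  p$extend <- FALSE
  m <- assemble_with_rotation(reads, g$seq, p, rotate_k = 300, seed = 2)
  expect_identical(m$seq, g$seq)
  expect_true(m$complete)
})

test_that("coverage report reproduces the reads x mean-length arithmetic", {
  expect_equal(coverage_report(reads_used = 6008,
                               mean_read_len = 448)$approx_bp, 2691584)
  expect_equal(coverage_report(reads_used = 442600,
                               mean_read_len = 95)$approx_bp, 42047000)
  expect_equal(coverage_report(reads_used = 0,
                               mean_read_len = 523)$approx_bp, 0)
  g <- circular_genome("c", random_seq(400, seed = 97))
  reads <- simulate_reads(g, clean_profile(60, 0), seed = 98,
                          yield_reads = 100)
  p2 <- preset_map_params("multiplex_rescue")
  p2$extend <- FALSE   # reference-bounded: report on the fixed 400 bp frame
  r <- iterative_bait_assemble(reads, g$seq, p2, seed = 1)
  rep <- coverage_report(r, mean_read_len = 60)
  expect_equal(rep$length, 400)
  expect_equal(rep$mean_cov, mean(r$coverage))
})
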