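# mitopool

Reconstructing circular mitochondrial genomes from multi-platform,
multiplexed sequencing data — and asking honestly how much phylogenetic
signal they carry.

`mitopool` is an R package for the computational chain behind
long-amplicon multiplex mitogenomics of small species radiations. The
experimental design it serves pools long-range PCR amplicons (two
overlapping fragments per ~16 kb circular mitogenome) from hundreds of
samples into a single *non-indexed* sequencing run: no barcode says which
read belongs to which animal, so every downstream step has to work from
sequence similarity alone. The package provides:

* **Windowed read binning** for non-indexed pools: partition a reference
  alignment into circular windows of homogeneous divergence
  (`sliding_pdistance_profile()`, `partition_by_divergence()`,
  `validate_windows()`), build per-window consensus references, and pull
  reads whose mismatch fraction clears the window's threshold — the
  window's maximum p-distance plus an additive allowance
  (`compute_threshold()`, `extract_reads()`).
* **Iterative reference-baited assembly** of circular genomes
  (`iterative_bait_assemble()`), with the reference-rotation protocol
  (`assemble_with_rotation()`, `rotate_reference()`) that repairs the
  linearisation edge artifact: a linear reference cannot place reads that
  span the circle's origin, so a single run leaves a terminal segment
  unrecovered; merging runs against the original and a rotated reference
  recovers the full circle.
* **Cross-platform error accounting**: align several reconstructions of
  one specimen (`align_reconstructions()`) and call *phantom single
  nucleotides* — insertion-type errors typical of homopolymer-challenged
  chemistries — against the cross-platform consensus (`call_phantoms()`,
  `phantom_rate()`, `gc_percent()`).
* **Composition-robust distances**: the LogDet/paralinear distance
  `d = -(1/4) [ln det F − (1/2) ln(det Dx · det Dy)]` (with `F` the joint
  site-pattern frequency matrix and `Dx`, `Dy` the marginal base
  frequencies), which stays additive when base composition drifts across
  lineages (`logdet_distance()`), a chi-square test of composition
  homogeneity (`composition_chi2()`), minimum-evolution trees via
  neighbor joining (`nj_me_tree()`) and a column bootstrap
  (`bootstrap_trees()`).
* **Exhaustive split-support interrogation** of tree samples: reduce a
  radiation to a small-taxon problem by rooting and collapsing proven
  clades (`reduce_taxa()`), enumerate *all* possible clades (2^n − n − 2)
  and rooted topologies ((2n−3)!!) (`enumerate_clades()`,
  `enumerate_rooted_trees()`), and report frequency-of-occurrence support
  for full and partial splits (`full_split_support()`,
  `partial_split_support()`, `support_table()`).
* **Synthetic data with full ground truth** for every stage: genomes
  evolved on a tree with optional lineage-specific composition drift and
  indels (returning the *true* alignment), platform-profiled read sets,
  non-indexed amplicon pools, and tree samples with controlled clade
  frequencies (`simulate_genomes()`, `simulate_reads()`,
  `simulate_pool()`, `simulate_treeset()`).

## Worked example

Simulate a two-taxon non-indexed pool (target at ~4% divergence from the
reference, decoy at ~40%), distil it, reconstruct the target's circular
genome with the rotation protocol, and summarise a synthetic posterior:

```r
library(mitopool)

spec <- evolution_spec("(T:0.02,D:0.55);", seed = 101)
g    <- simulate_genomes(spec, 4000)

prof <- platform_profile("hiseq", sub_error_rate = 0.002)
pool <- simulate_pool(g$genomes, prof, reads_per_amplicon = 150, seed = 102)
nrow(pool$reads)
#> [1] 1200

kept <- extract_reads(pool, g$genomes$T$seq,
                      threshold = compute_threshold(0.05, 0.10), seed = 103)
attr(kept, "stats")
#>    n_input n_retained
#>       1200        600
mean(kept$truth$source_taxon == "T")     # precision against truth labels
#> [1] 1

p <- preset_map_params("multiplex_initial")
p$extend <- FALSE                        # reference-bounded runs
rec <- assemble_with_rotation(kept, g$genomes$T$seq, p,
                              rotate_k = 1000, seed = 104)
rec
#> <reconstruction> specimen [NA]: 4000 bp, mean coverage 14.3x, complete
identical(rec$seq, g$genomes$T$seq)
#> [1] TRUE

ts <- simulate_treeset(c("A", "B", "L", "R"), 1000,
                       clade_targets = c("A,B" = 0.7, "L,R" = 0.55),
                       seed = 105)
support_table(list(`synthetic posterior` = ts))
#>                       AB   AL AR BL BR   LR  ABL ABR ALR BLR
#> synthetic posterior 69.7 30.3  -  -  - 53.1 46.9   -   -   -
```

The extraction keeps exactly the 600 target reads (perfect recall and
precision at this divergence separation); the merged assembly is the full
4,000 bp circle, identical to the simulated truth; and the support table
reports every possible clade of the four-taxon problem, with the
configured 70% / 55% clade frequencies recovered up to sampling error and
zeros printed as dashes.

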