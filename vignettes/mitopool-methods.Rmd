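---
title: "Methods: from pooled reads to split support"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from pooled reads to split support}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitopool)
```

`mitopool` implements the computational chain of a multi-platform
mitogenome sequencing study of a small species radiation: binning reads out
of a non-indexed multiplex pool, reconstructing circular mitogenomes by
reference-baited iterative mapping, reconciling reconstructions of one
specimen across platforms, and summarising phylogenetic support over
samples of trees. This vignette explains each model and procedure, the
parameters that matter, and the choices made where the design was open.

## The study design being modelled

Long-range PCR amplifies each ~16 kb circular mitogenome in two
overlapping fragments (roughly 6.4 kb and 10.7 kb). Amplicons from
hundreds of animals are pooled *without* per-sample index barcodes and
sequenced on several platforms (Illumina HiSeq/MiSeq, Roche 454, Ion
Torrent). Nothing in a read identifies its sample: taxon assignment must
come entirely from sequence similarity to references. Separately,
individually indexed shotgun libraries are sequenced on MiSeq and
assembled by reference baiting. The synthetic-data module reproduces this
design end to end with known truth, which is what makes the pipeline
testable at all.

## Synthetic data

`simulate_genomes()` evolves a root sequence along a rooted tree with
branch lengths in expected substitutions per site. Two substitution
processes are available: a stationary GTR model, and an F81-style process
whose target base frequencies can differ per lineage
(`substitution_model(lineage_freqs = ...)`). The second is deliberately
non-reversible: each listed branch drifts toward its own composition,
which is the simplest mechanism that produces the base-composition
heterogeneity that motivates LogDet distances, and is sufficient to make a
chi-square homogeneity test reject and a stationarity-assuming distance
correction go biased. Indels are Poisson events (rate per site per unit
branch length, lengths geometric, capped at 10); the simulator tracks
column identities through the tree, so the *true* multiple alignment is
returned alongside the leaf genomes and no aligner is needed downstream.

`simulate_reads()` draws fragments from circular coordinates — reads may
span the origin, in which case they are emitted as contiguous strings from
the doubled genome and their truth labels record the wrapped interval.
Platform profiles carry the observed mean read lengths of the four
platforms (MiSeq 448 bp, HiSeq 95 bp, 454 523 bp, Ion Torrent 98 bp).
Error rates are free parameters because the study data do not constrain
them directly; defaults are 0.2% substitutions per base everywhere and a
0.5% per-homopolymer-run single-base length error for the 454 and Ion
Torrent chemistries (the mechanism behind "phantom" nucleotides), zero for
the Illumina chemistries. Quality strings are constant — quality realism
is out of scope. Paired profiles emit mates with a `/1` / `/2` id
convention; downstream stages treat mates independently, as the study
pooled paired data per sample before assembly.

`simulate_pool()` applies a per-taxon two-fragment amplicon scheme
(circular intervals; any amplicon can be flagged failed, emulating the
real failure where one taxon kept only the short amplicon and thus ~one
third of its genome), generates reads per amplicon, strips all sample
information from the read ids, and keeps the truth table separately.

`simulate_treeset()` draws i.i.d. rooted topologies from a distribution
over the complete enumerated topology set. Given *clade* targets instead
of topology probabilities, it solves for a distribution by non-negative
least squares over the clade-by-topology incidence matrix (with a heavily
weighted sum-to-one constraint) and rejects targets that no distribution
can realise, reporting the closest achievable frequencies. Empirical clade
frequencies then converge to the targets at the usual $\sqrt{p(1-p)/n}$
rate, which the tests exploit.

## Windowed reduction of a non-indexed pool

A reference alignment of a few published relatives is scanned with
`sliding_pdistance_profile()`: for every window start, the maximum over
taxon pairs of the p-distance (proportion of differing sites, pairwise
deletion of gaps/N) inside the window, with circular wrap.
`partition_by_divergence()` segments this profile greedily: a block is
closed when admitting the next value would push the within-block
divergence range over `range_tol` (default 0.05) and the block already has
`min_block` columns. Boundaries are then widened so consecutive windows —
including last-to-first on the circle — overlap by `min_overlap` columns
(50 bp in the motivating design), so reads sitting on a boundary cannot
fall between windows. The original partition was drawn by eye; the
algorithm here only has to satisfy the validator
(`validate_windows()`: minimum circular consecutive overlap and coverage)
and divergence homogeneity, not reproduce any particular boundary set.

Each window gets a majority consensus (`window_consensus()`; ties become
IUPAC codes, gap-majority columns are dropped so the reference is
mappable) and a mismatch threshold: the window's maximum p-distance plus
an allowance (`compute_threshold()`). A "10% allowance" is read as
**additive percentage points** (0.22 → 0.32); the multiplicative reading
(0.22 → 0.242) barely moves the threshold and would defeat the stated aim
of pulling every target read, but it is available via
`mode = "multiplicative"`.

`extract_reads()` retains a read iff its best placement on the window
consensus — either strand, k-mer seeded (word length 14), with a gapped
Smith–Waterman fallback under the preset's gap constraints (15% gaps per
read, single gap ≤ 50) — has a substitution mismatch fraction at or below
the threshold. Indels are constrained separately and never counted as
mismatches, since the source protocol listed gap limits as separate
parameters. Raising the threshold can only retain more reads
(monotonicity), a property the tests assert.

## Iterative baited assembly and the rotation protocol

`iterative_bait_assemble()` is a transparent reimplementation of the
baiting idea, not of any particular assembler's internals: map all reads
to the current reference (k-mer seeds, ungapped scoring with a gapped
fallback), replace the reference with the per-column majority of mapped
bases, and repeat until nothing changes. Positions never covered by any
read keep the bait base for the *next* mapping round (so flanking reads
can erode a diverged patch from its edges) but are reported as `N` in the
output — the reader should never mistake bait sequence for evidence.
Consensus ties become IUPAC codes in the output; placement ties are broken
by a seeded RNG so runs are reproducible.

Two mapping modes matter:

* **Reference-bounded** (`extend = FALSE`): every read must lie entirely
  within the reference. With a full-length linearised circular reference
  this is the configuration that produces the classic edge artifact: reads
  spanning the circle's origin have no contiguous image on the linear
  reference and are discarded, so coverage decays to zero within roughly a
  read length of the ends and the terminal segment comes out as `N`.
* **Extending** (`extend = TRUE`): reads may overhang an end if at least
  half the read (and never fewer than `anchor_min` bases) anchors inside,
  and the overhang consensus grows the reference by at most half a read
  length per end per iteration — the cap prevents runaway chimeric
  extension. From a short seed window the assembly walks around the whole
  circle and stops naturally once it is about one read longer than the
  genome, because from then on every read has a better full-length
  placement than any clipped one.

`assemble_with_rotation()` is the repair for the edge artifact: run the
reference-bounded assembly twice, once against the reference as given and
once against `rotate_reference(ref, k)` (default k = 1000, i.e. the last
1000 bases moved to the front), derotate the second run back, and merge
per position — an `N` yields to the other run's call, conflicting calls
are settled by coverage with ties becoming ambiguity codes, and coverage
is combined as the per-base maximum. Each run's blind spot lies in the
other run's interior, so the merge recovers the complete circle; on
error-free synthetic reads at 20× it reproduces the truth exactly. When
the two runs disagree in length they are globally aligned first and
columns where either run has an end gap are trimmed — the merge rule for
that situation is not specified by the source protocol, so this
conservative reading is a documented guess. If the runs share fewer than
`2 * rotate_k` agreeing bases the longer run is returned with a warning
flag rather than a forced merge.

Presets mirror the documented mapping parameter sets:
`multiplex_initial` (3% mismatches per read, max gap 15, ambiguity 1,
100 iterations, ties placed randomly), `multiplex_rescue` (1% mismatches,
ambiguity 2 — the stricter conspecific-reference pass that accommodates
intraspecific variation), and `hiseq_extract` (15% gaps, gap ≤ 50, word
length 14, ambiguity 4, single pass; the mismatch threshold comes from
the window).

## Cross-platform concordance and phantom nucleotides

`align_reconstructions()` derotates near-identical reconstructions of one
specimen to a common origin (best circular match of an unambiguous probe)
and builds a reference-anchored multiple alignment: every sequence is
globally aligned to the first, insertions opening shared gap columns.
Inputs sharing less than 50% identity are rejected as a likely specimen
mix-up. This anchored construction is appropriate precisely because the
inputs are reconstructions of the *same* molecule; it is not a general
MSA.

`call_phantoms()` operationalises a *phantom single nucleotide* as an
insertion-type disagreement: a column where the focal platform's row has a
base but the majority of the other rows (ignoring N votes) have a gap.
Counts are tallied under the focal base. Two rows need interpretation
because the source tables do not define them: the `N` row counts focal `N`
calls where the others agree on a base; `insertions_added` counts phantom
columns where the base ties or beats the gap once the focal row votes —
i.e. errors that made it into the specimen consensus — and these are
excluded from the phantom totals, which reproduces the worked rates (0.28%
= 15/5,406; 0.43% = 46/10,746; 0.05% = 8/15,540) exactly.
Substitution-type disagreements are reported separately and never counted
as phantoms. Rates are rounded half-up to two decimals, GC% to one, the
printed conventions. Adjacent phantoms inside one homopolymer run count
per inserted base; conversely, an injected base that merely lengthens an
existing run coalesces with it, so the gap column can shift within the
run — the injection tests therefore avoid run-internal positions.

## Distances, composition, bootstrap

`logdet_distance()` implements the paralinear/LogDet distance
$d = -\tfrac14\left[\ln\det F - \tfrac12 \ln(\det D_x \det D_y)\right]$,
with $F$ the joint relative-frequency matrix of aligned site patterns and
$D_x, D_y$ the diagonal marginal-frequency matrices; pairwise deletion of
gaps/N, and the $-\tfrac14$ four-state scaling (users comparing against
software that uses the unscaled paralinear convention should rescale). It
is zero on identical sequences regardless of composition, symmetric, and
— the property that matters — additive in expectation under arbitrary
non-stationary Markov evolution, which the tests verify against the
closed-form expected joint distribution of a drifting-composition process
while showing the Jukes–Cantor correction biased on the same data. A
singular $F$ (e.g. a base absent from one sequence) yields a flagged `NA`
rather than a number.

`composition_chi2()` is the classic contingency-table homogeneity test on
the taxa × base count table from non-gap, non-N sites (df =
(taxa−1)(bases−1), upper-tail p). Ambiguity codes are excluded entirely;
how the original desktop software treats them is unknown, so the simplest
defensible convention is used and stated.

`nj_me_tree()` realises the minimum-evolution criterion with
neighbor joining (the standard heuristic; an exhaustive ME search would
not change what is testable here) and `bootstrap_trees()` resamples
alignment columns with replacement, one tree per replicate, redrawing
replicates whose LogDet matrix is singular and recording how many. One
caveat: on data with no signal NJ still returns an arbitrarily *resolved*
topology with zero-length internal branches, so a bootstrap of identical
sequences does not produce a star tree — support summaries of such input
are meaningless, and the tests exercise the informative regime instead.

## Tree samples, reduction, and split support

`reduce_taxa()` performs the small-taxon reduction: root every tree on a
designated outgroup, verify each collapse set is monophyletic (by default
in *every* tree; `tol` admits a fraction of failures, and a rejection
reports the observed failure rate), replace each set by one leaf, and drop
the outgroup — what remains is the rooted problem on the surviving taxa.
For four taxa that problem has exactly $2^4 - 4 - 2 = 10$ possible clades
and $(2\cdot4-3)!! = 15$ rooted binary topologies, which
`enumerate_clades()` and `enumerate_rooted_trees()` generate explicitly
(stepwise leaf addition, canonical sorted-newick form, guarded above
n = 9 where enumeration stops being useful).

`full_split_support()` reports, for every possible clade, the percentage
of trees containing it, and for every possible topology its frequency —
frequencies over resolved trees sum to 100% and each clade's support
equals the sum over topologies containing it, an identity the tests check
exhaustively for n = 4. `partial_split_support()` prunes each tree to a
taxon subset (retaining the rooting) before checking the clade, the
frequency-of-occurrence reading of partial-split support; pruning can
only preserve or create a display, never destroy one, so partial support
is bounded below by the corresponding full support. Trees with polytomies
neither support nor conflict with a clade and the denominator stays the
sample size. `support_table()` lays analyses × clades out with
percentages to one decimal and zeros rendered as "–". Topology indices in
the output follow canonical order and will not match any particular
figure's hand-drawn ordering.

## Numerical conventions and problem sizes

Rounding of reported percentages is half-up at the printed precision
(2 dp for phantom rates, 1 dp for GC% and support). Consensus ties are
IUPAC codes everywhere; zero-coverage positions are `N`. All stochastic
functions take an explicit `seed` and restore the caller's RNG state.

The test and acceptance workloads are sized for a single CPU: assembly
recovery runs on a 6 kb circular genome at 20× with 95 bp reads (plus a
3 kb seed-window growth case), the LogDet additivity check uses 30
replicates of 10 kb alignments, extraction pools 400 reads of 95 bp, and
tree-sample round-trips use 10,000 trees. These are the package's choices
of demonstration scale; the algorithms themselves have no such limits,
though the pure-R mapper is comfortable at tens of thousands of reads
rather than millions — distilling a full lane is the job of the windowed
extraction exactly because it cuts the problem down before assembly.

## Known limitations

* The mapper evaluates ungapped placements first and falls back to a
  banded gapped alignment; consensus columns are accumulated from the
  ungapped interpretation of each placement, so dense indel errors blur
  rather than shift the consensus. Majority voting absorbs this at the
  error rates modelled here.
* A reference patch diverged well beyond the mismatch preset in *both*
  rotation runs (a locally hypervariable region against a heterospecific
  bait) can survive as `N` — the rescue preset against a conspecific
  reference is the intended remedy, mirroring the two-pass design it is
  named after.
* Base-composition drift is modelled with lineage-specific F81 targets;
  real compositional evolution is richer, so passing the LogDet suite
  shows consistency under this mechanism, not under every non-stationary
  process.
* The generators emulate read lengths, homopolymer indels, pooling and
  amplicon failure, but not chimeras, contamination, quality decay along
  reads, or coverage biases; conclusions from synthetic tests transfer to
  real data only to the extent those factors do not dominate.
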