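Package: mitopool
Title: Mitogenome Reconstruction and Phylogenetic Support from Multiplexed
    Sequencing Pools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing circular mitochondrial genomes from
    multi-platform next-generation sequencing data and for interrogating the
    phylogenetic signal they carry. Implements divergence-windowed extraction
    of taxon reads from non-indexed pooled amplicon data, iterative
    reference-baited assembly with a reference-rotation correction for the
    linearisation edge artifact, cross-platform phantom-nucleotide error
    accounting, LogDet/paralinear distances with base-composition
    heterogeneity testing and column bootstrap, and exhaustive full and
    partial split-support summaries over samples of rooted trees. A
    synthetic-data module simulates circular genomes evolved on a tree,
    platform-specific read sets, pooled amplicon mixtures and tree samples
    with controlled split frequencies, with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
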