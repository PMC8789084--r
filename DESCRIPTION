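Package: traelkit
Title: Replication Fork Directionality Profiling from 3'-End Break Mapping Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for TrAEL-seq style sequencing libraries that map
    free DNA 3' ends (replication forks, strand breaks) at single-nucleotide
    resolution. Covers UMI and poly-T pre-processing of raw reads, optional
    sequence-based deduplication for tandem multi-copy loci, reference masking,
    exact-match alignment of synthetic fixtures plus SAM import, UMI-aware
    alignment deduplication, strand-specific running-window quantification with
    blacklist filtering and reads-per-million / trimmed-mean enrichment
    normalisation, read-polarity (R-F)/(R+F) profiles with replication-origin
    and fork-convergence calling, a negative-binomial windowed differential
    test for fork stalling, and phenotype statistics (tandem-repeat CNV
    percentages, dose-response area-under-curve, ANOVA with Sidak correction).
    Includes a replication-fork read simulator that provides ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Rsamtools,
    methods,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    edgeR,
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
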