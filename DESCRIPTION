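Package: cherscan
Title: ChIP-Chip Tiling-Array Analysis of Transcription-Factor Binding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for two-colour promoter tiling-array
    (ChIP-chip) data: probe ingest and log2 IP/input ratios, removal of
    non-uniquely mapping reporters, Tukey-biweight scale normalization,
    position-window running-median smoothing, quantile-threshold detection
    of ChIP-enriched regions (chers) with run merging and scoring,
    promoter/gene assignment with strand-aware TSS distances, Match-style
    position-weight-matrix scanning (matrix and core similarity scores),
    and DAG-aware hypergeometric over-representation analysis with
    Benjamini-Hochberg FDR. Includes a fully deterministic synthetic-data
    generator (genome, gene models, probes, spiked intensities, planted
    motifs, annotation sets) with ground truth for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    igraph,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
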