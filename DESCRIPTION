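Package: seasonwheel
Title: Seasonal Oscillation, Module and Redundancy Analysis for Marine
    Microbiome Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing multi-year, irregularly sampled marine
    microbiome time series. Detects annually oscillating amplicon sequence
    variants (ASVs) and gene clusters by Fourier reconstruction of their
    abundance signals, quantifies inter-annual recurrence of peak timing and
    order, builds co-oscillation correlation networks with Louvain module
    detection and environmental coupling, structures gene clusters within
    functions (redundancy, diversity-abundance coupling, dominance turnover),
    computes iterated-rarefaction alpha diversity, Hellinger/Bray-Curtis
    ordination with convex-hull cohesion, and 80% truncated average depth
    (TAD80) transcription summaries. Includes a synthetic seasonal-community
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    vegan,
    data.table,
    rtracklayer,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
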