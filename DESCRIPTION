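Package: spacon
Title: Consensus Clustering and Entropy Diagnostics for Spatially Aware
    Clustering Results
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for combining and diagnosing clustering results of
    spatial omics data (spots, bins or cells with 2-D coordinates).
    Implements smoothness entropy and cross-method entropy with Hungarian
    label alignment, pairwise agreement matrices (ARI/NMI), base-clustering
    selection rules (class-imbalance filtering, smoothness ranking with
    per-algorithm deduplication, concordance-block detection), three
    consensus algorithms (K-modes, latent class analysis by EM, and a
    weighted Jensen-Shannon-divergence co-association consensus partitioned
    with Leiden), leave-one-out pseudo-ground-truth validation, granularity
    sweeps, and a synthetic lattice-tissue generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    clue,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
biocViews: Clustering, Spatial, Transcriptomics, SingleCell
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
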