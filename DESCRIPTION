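Package: msca
Title: Multi-View Subspace Clustering of Multi-Omics Sample Profiles
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrative clustering of samples profiled by two or more omics
    data types (e.g., gene expression and copy number). Each data type is
    summarised as a sample-by-sample affinity matrix obtained from a
    locality-constrained low-rank representation model solved by a linearized
    alternating-direction method with adaptive penalty; the per-view
    affinities are then fused by cross-view graph diffusion in the style of
    similarity network fusion, and the fused network is partitioned with
    Ratio-Cut spectral clustering. Includes a synthetic multi-view benchmark
    generator with planted cluster structure, view-specific merged clusters
    and tunable noise, plus adjusted Rand index and silhouette evaluation
    utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
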