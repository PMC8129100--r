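Package: neuroaggsim
Title: Agent-Based Simulation and Morphometry of Neuron-Astrocyte
    Aggregation in Confined 3D Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates aggregation, contraction, clustering and
    differential-adhesion sorting of neurons and astrocytes in confined
    three-dimensional cultures with a point-cell model driven by
    exponential attraction, repulsion, substrate adhesion and gravity.
    Provides the morphometric descriptors used to characterise such
    cultures (cell-to-cell distance profiles, cluster segmentation,
    contraction, depth-resolved astrocyte ratios), image-based process
    directionality detection via 2D autocorrelation, nucleus axis and
    height morphometry, calcium-trace baseline correction and burst
    metrics, local field potential burst-initiation analysis, and seeded
    synthetic-data generators for all analysis inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    signal,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
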