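Package: winnowkan
Title: Kolmogorov-Arnold Networks with a Gene-Selecting Winnow Layer for
    Spatial Location Recovery
Version: 0.1.0
Authors@R: person("winnowkan", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Supervised recovery of spatial information for single-cell
    RNA-seq queries from a spatial transcriptomics reference.  Implements
    Kolmogorov-Arnold networks whose edges carry trainable B-spline plus
    SiLU activations with adaptive, data-driven grids; a first-layer
    "Winnow" selector that scores gene importance through the spline
    weights and drives a two-stage fit on a reduced gene set; task heads
    for 2D coordinate regression, rank-consistent (CORAL) ordinal layer
    recovery, and categorical domain recovery; evaluation metrics
    (distance errors, pairwise-distance Pearson correlation, top-1/top-2
    accuracy); seeded negative-binomial simulators of layered and
    gradient tissues; MatrixMarket/delimited readers and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
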