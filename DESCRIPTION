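Package: NitocraSim
Title: Individual-Based Life-Cycle Simulation of the Copepod Nitocra
    spinipes under Temperature and Food Limitation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stage-structured, individual-based simulation of the life
    cycle of the brackish-water harpacticoid copepod Nitocra spinipes.
    Development, survival and reproduction of individual animals are
    driven by empirical temperature response functions (exponential
    decay, Belehradek and quadratic optimum curves) and by food
    limitation expressed through Holling type-III ingestion of benthic
    algal carbon, with minute-resolution food depletion and competition
    in microplate wells. Includes Monte-Carlo replication with
    percentile confidence bands, ready-made development- and
    reproduction-test experiments, an exact Freeman-Halton test for
    r x 2 contingency tables by complete enumeration, and packaged
    coefficient tables and experiment fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
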