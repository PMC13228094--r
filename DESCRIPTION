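Package: emaconn
Title: Individual-Specific Functional Networks and Bayesian Ordinal Models
    for Ecological Momentary Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking ecological momentary assessment (EMA) ratings of
    motivation and pleasure to individual-specific resting-state functional
    network metrics. Implements template-matching network mapping on surface
    vertex time series (dense vertex connectivity, top-fraction binarization,
    Dice matching to network templates, small-patch removal and contiguity
    parcellation), network-level graph metrics (Fisher-Z within/between-network
    connectivity, participation coefficients over tie-density grids, spatial
    extent), EMA compliance filtering and model-table assembly, and Bayesian
    hierarchical cumulative-logit regression with credible-interval,
    probability-of-direction and ROPE decision rules, including simple-slopes
    contrasts and secondary between-network models. A synthetic-data module
    generates surface geometry, block-correlated BOLD-like time series and
    ordinal EMA responses from a known generative model so the full pipeline
    can be exercised against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    coda,
    igraph,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    rjags
Config/testthat/edition: 3
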