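Package: rrwasym
Title: Hemispheric Asymmetry Detection in Directed Brain Networks via Return Random Walks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds directed weighted brain-connectivity graphs from region-wise
    BOLD-like time series using time-lagged cross-correlations, preconditions them
    with a neural-embedding plus Katz-modulated Laplacian regularization step
    (net4Lap), filters structural noise with a directed Return Random Walk link
    predictor, quantifies left-right hemispheric asymmetries through in/out-degree
    imbalance of paired regions of interest, and evaluates two-group discrimination
    with linear discriminant analysis under stratified cross-validation. Includes a
    synthetic-cohort generator (random digraphs with controlled density, planted
    hemispheric asymmetry, and lagged time series) so the whole pipeline is testable
    without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
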