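Package: symptomnet
Title: Symptom Network Analysis for Ordinal Psychiatric Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation and comparison of regularized partial-correlation
    (Gaussian graphical model) symptom networks from ordinal questionnaire
    data. Provides EBIC-selected graphical lasso estimation, node centrality
    indices (strength, expected influence, closeness, betweenness),
    non-parametric bootstrap edge-accuracy intervals, case-dropping
    stability with correlation-stability coefficients, permutation-based
    two-group network comparison tests, nodewise predictability, summary
    statistic tests for group tables, and a Gaussian-copula generator of
    ordinal symptom data with known network structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    tools,
    jsonlite,
    MASS,
    mvtnorm,
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
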