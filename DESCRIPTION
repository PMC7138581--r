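Package: fcgraph
Title: Graph-Theoretical Group Comparison of Functional Brain Networks
Version: 0.1.0
Authors@R:
    person("fcgraph", "developers", email = "fcgraph@example.org", role = c("aut", "cre"))
Description: Construction and group-level comparison of functional brain
    networks from regional time series. Builds Pearson connectivity
    matrices, binarizes them over a sparsity grid, computes global and
    local efficiency, clustering coefficient, characteristic path length
    and degree centrality, normalizes clustering and path length against
    degree-preserving (Maslov-Sneppen) random reference networks to obtain
    the small-world coefficients gamma, lambda and sigma, classifies edges
    into rich-club, feeder and local connections around degree-centrality
    hubs, and performs between-group inference (two-sample t-tests with
    Benjamini-Hochberg FDR, permutation tests on connection strengths,
    Spearman clinical correlations). Includes a synthetic cohort generator
    with modular covariance, planted hubs and controllable group effects
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
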