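Package: ditree
Title: IRTree Models with Co-Occurring Dominance and Ideal-Point Response Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing Likert-type rating responses with item response
    tree (IRTree) models whose sub-decisions may depend on several latent
    response processes at once. Pseudo-items are parameterized by a
    multidimensional divide-by-total model in which dominance processes
    (generalized partial credit model) and ideal-point processes (generalized
    graded unfolding model) co-occur within a single category distribution.
    Includes builders for response-style trees on four-, five- and six-point
    scales, a synthetic-data generator for recovery studies, Bayesian
    estimation by adaptive Metropolis-within-Gibbs with compiled likelihoods,
    rank-normalized convergence diagnostics, Pareto-smoothed importance
    sampling leave-one-out model comparison, and a joint linear mixed model of
    log response times with tree-derived predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda,
    optparse,
    withr
Config/testthat/edition: 3
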