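Package: rglmens
Title: Random Generalized Linear Model Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bootstrap-aggregated generalized linear models with per-bag
    random feature subspaces, optional interaction terms, univariate
    candidate screening and forward selection by AIC ("random GLM"
    ensembles). Provides out-of-bag accuracy estimation, ensemble variable
    importance measures, importance-based predictor thinning with the
    expected sparsity curve, repeated stratified k-fold cross-validation,
    JSON model serialization, a command-line interface, and seeded
    generators for module-structured gene-expression data and the
    classical ringnorm/twonorm/threenorm Gaussian benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
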