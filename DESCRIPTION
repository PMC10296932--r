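Package: pbsis
Title: Two-Stage Point-Biserial Sure Independence Screening for
    High-Dimensional Binary-Response Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Feature screening and variable selection for
    high-dimensional generalized linear models with a binary response.
    Stage one ranks predictors by the absolute point-biserial
    correlation with the response and retains the top d (PB-SIS);
    stage two fits a penalized logistic regression (lasso, SCAD or
    MCP) on the retained predictors by iteratively reweighted least
    squares with coordinate descent, with the tuning parameter chosen
    by cross-validation, AIC, BIC or EBIC.  Includes the marginal
    maximum-likelihood (MMLE) and Kolmogorov-filter comparator
    screens, a synthetic-data generator for autoregressive Gaussian
    designs with sparse logistic (or probit) truth, and Monte-Carlo
    study drivers reporting screening and selection accuracy (P1, P2,
    minimum model size, MMMS, RSD, mean model size).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
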