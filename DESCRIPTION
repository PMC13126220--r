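Package: metacfa
Title: Meta-Analytic Confirmatory Factor Analysis with Mean Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: One-stage meta-analytic structural equation modeling (MASEM) of
    study-level covariance matrices and mean vectors. Study summary statistics
    are combined in a multivariate random-effects meta-analysis whose average
    effect sizes are restricted to the model-implied moments of a confirmatory
    factor model with a mean structure. Model parameters may be moderated by
    study-level variables (the regression approach), which supports tests of
    configural, weak, and strong (partial) factorial invariance across groups
    of studies and the comparison of latent means. Includes marginal maximum
    likelihood estimation with analytic gradients, likelihood-ratio and Wald
    tests, AIC/BIC/RMSEA model comparison, a Monte-Carlo evaluation harness,
    and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
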