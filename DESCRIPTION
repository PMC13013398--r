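Package: rngxe
Title: Hierarchical One-Step Reaction Norm Models for Genotype-by-Environment
    Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint Bayesian estimation of contemporary-group environmental
    effects and animal-specific intercept/slope breeding values under a
    hierarchical one-step reaction norm model, as used in pedigree-based
    genetic evaluation of beef cattle. Provides a Gibbs sampler with an
    inverse numerator-relationship-matrix genetic prior, data-editing rules
    for contemporary-group size and sire progeny counts, environmental
    gradient construction from posterior contemporary-group solutions,
    gradient-wise additive variances, heritabilities and genetic
    correlations from the intercept/slope covariance function, and
    classification of sires by environmental sensitivity. A synthetic-data
    module simulates pedigreed multi-herd populations with known parameters
    for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    coda,
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
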