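Package: hetvar
Title: Detecting Variance Effects of Covariates on Quantitative Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for discovering variance quantitative trait loci (vQTLs)
    and, more generally, covariates associated with the variance of a
    quantitative trait. Implements a Bayesian test for heteroskedasticity
    based on log10 Bayes factors computed by closed-form marginalization of
    the mean effect followed by a Laplace approximation over the remaining
    parameters; the classical Levene, Brown-Forsythe, Bartlett, correlation
    least squares (CLS) and iterative double-GLM comparison tests under one
    result contract; mean-effect-preserving permutation nulls with global and
    MAF-stratified false discovery rate calibration; a quantitative-trait
    simulator covering the ideal heteroskedastic model and four non-ideal
    trait families; a trait-distribution classifier built on one-sided
    Kolmogorov-Smirnov feature vectors with prescriptive transformations; and
    a precision-recall benchmarking harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    jsonlite,
    optparse
Config/testthat/edition: 3
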