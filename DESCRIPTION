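Package: ssblasso
Title: Scale-Space Bayesian LASSO for QTL Association Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Gibbs-sampled Bayesian LASSO (and Bayesian ridge) shrinkage
    regression for quantitative trait locus (QTL) association mapping,
    evaluated over a whole grid of tuning parameters in the spirit of
    scale-space analysis. Provides combined (sum and difference) effects for
    collinear markers, point-wise and simultaneous (highest point-wise
    probabilities) posterior sign-probability detection, phenotype-permutation
    calibration of the tuning-parameter threshold and of a lambda-dependent
    credibility level, quantized posterior-mean and credibility color maps,
    and a line-cross genotype/phenotype simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
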