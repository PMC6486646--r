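Package: mrspike
Title: Robust Two-Sample Mendelian Randomization by Mixture-Model Spike
    Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation of causal effects from paired GWAS summary
    statistics in the presence of widespread horizontal pleiotropy. The
    estimator (MRMix) models the per-SNP bivariate effect sizes with a
    four-component normal mixture and identifies the causal effect as the
    slope that maximizes the estimated null-component mass of the residual
    distribution, fit by a constrained two-component EM at each candidate
    slope. Includes harmonization and quality control of summary
    statistics, instrument selection, estimating-equation (sandwich)
    standard errors with a parametric-bootstrap validation oracle, the
    standard comparator estimators (inverse-variance weighted, Egger
    regression, weighted median, weighted mode), and a simulator for
    genome-scale replicate studies under several effect-size
    distributions.
License: MIT + file LICENSE
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
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
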