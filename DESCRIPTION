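Package: doserr
Title: Simulation and Correction of Shared and Unshared Dose Measurement
    Error in Radiation Epidemiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A simulation laboratory for assessing corrections for dose
    measurement error in grouped Poisson excess-relative-risk regression,
    as used in radiation epidemiology. Generates synthetic cohorts whose
    doses carry shared and unshared Berkson and classical lognormal errors,
    fits linear and linear-quadratic excess-relative-risk models by six
    methods (unadjusted regression, regression calibration, extended
    regression calibration, Monte Carlo maximum likelihood, quasi
    two-dimensional Monte Carlo with Bayesian model averaging, and
    frequentist model averaging), and evaluates coverage probability of
    profile-likelihood or posterior intervals and percent bias in the
    predicted excess relative risk across error scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
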