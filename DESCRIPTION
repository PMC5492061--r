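Package: pmical
Title: Inverse Prediction and Statistical Calibration for Postmortem
    Interval Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Confidence sets on insect age and carrion succession interval by
    inverse prediction (statistical calibration).  Implements an exact
    conservative multinomial matching test for categorical responses (life
    stage, species presence/absence), with rejection thresholds and minimum
    training sample sizes; inversion of regression prediction regions for
    continuous responses (larval length, width), univariate and multivariate;
    Bonferroni combination of categorical and continuous evidence; design
    evaluation by confidence-set coverage (random versus size-biased
    subsampling, covariate transfer, group F-tests); and stochastic simulators
    of larval growth cohorts and carrion succession for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
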