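Package: accmeta
Title: Meta-Analysis of Test Accuracy with Predictive Inference and
    Calibration Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for meta-analysis of diagnostic and prognostic test
    accuracy that go beyond pooled averages. Fits the bivariate binomial
    logit-normal random-effects model for sensitivity and specificity by
    adaptive Gauss-Hermite maximum likelihood or by MCMC, and turns the
    fit into statements about new populations: prediction intervals,
    joint prediction regions, and probabilities that sensitivity and
    specificity jointly exceed clinically acceptable values. Derives
    post-test probabilities (PPV and NPV) for a target population by
    three strategies (pooled prevalence, local prevalence, or a
    bivariate meta-regression of PPV and NPV on prevalence) and
    validates their calibration with internal-external cross-validation:
    observed/expected ratios are meta-analysed across leave-one-study-out
    cycles, with an exact binomial offset model for cycles with zero
    events. Also pools c statistics across studies with bootstrap
    standard errors and random-effects prediction intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    rjags,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    lme4,
    glmmTMB,
    metafor,
    jsonlite,
    optparse
Config/testthat/edition: 3
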