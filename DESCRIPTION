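Package: trajsmm
Title: Latent Trajectory Classification via Smoothing Mixture Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies longitudinal trajectories into latent classes with a
    hard-assignment expectation-maximization algorithm in which each class
    mean is a penalized B-spline (P-spline) smoother, the smoothing mixture
    model (SMM). Supports class-count selection by the Bayesian information
    criterion with a parsimony margin, relabeling of classes by trajectory
    level, concordance cross-tabulation against baseline groupings, and
    estimation of crude and adjusted odds ratios of binary outcomes across
    trajectory classes by logistic regression with a univariate p < 0.2
    confounder screen. Includes a synthetic-cohort generator emulating
    monthly maternal-weight measurements over pregnancy with latent weight
    classes, a shared gain curve, subject random intercepts and
    outcome-class links, so the full pipeline can be exercised and validated
    without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite,
    yaml,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    ggplot2,
    optparse
Config/testthat/edition: 3
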