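Package: trophicbrain
Title: Brain Hierarchy from Generative Effective Connectivity and Trophic Levels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates directed whole-brain networks from resting-state BOLD
    time series with a linearized Hopf (Stuart-Landau) model fitted by a
    non-reversibility-aware pseudo-gradient, and characterizes their
    hierarchical organization through trophic levels, trophic incoherence and
    directedness. Includes a synthetic multi-site cohort generator with planted
    hierarchy flattening, empirical-Bayes (ComBat-style) multi-site
    harmonization, Centiloid conversion of amyloid-PET uptake ratios,
    covariate-adjusted permutation statistics, mixed-effects ridge regression,
    and an mRMR + logistic-regression disease-staging classifier with
    Monte Carlo evaluation, permutation significance and linear Shapley
    feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    igraph,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sva,
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
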