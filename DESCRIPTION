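Package: attractr
Title: Attractor Dynamics and Recurrence Analysis of Longitudinal Biomarker
    Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing dynamical attractor systems in long,
    densely sampled biomarker time series such as elemental profiles measured
    along tooth dentine growth increments. Implements Takens delay embedding
    with mutual-information delay selection and false-nearest-neighbour
    dimension selection; recurrence quantification analysis with an adaptive
    distance threshold fixed at a target recurrence rate, yielding
    determinism, mean diagonal length, and diagonal-line entropy; potential
    energy landscape estimation from the empirical density via the
    steady-state Fokker-Planck relation, with quasi-stable state and tipping
    point detection; stochastic (Langevin) and regime-switching simulators
    for generating synthetic cohorts with planted case/control differences;
    and downstream group comparisons (Poisson and linear models with FDR
    control) and disease classification (penalized logistic regression and
    gradient-boosted trees with bootstrap ROC inference and rank-based tests
    of AUC against chance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    glmnet,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
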