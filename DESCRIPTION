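Package: dfncstates
Title: Dynamic Functional Network Connectivity States from Sliding-Window fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dynamic functional network connectivity
    (dFNC) of resting-state fMRI component time courses: tapered sliding-window
    covariance with graphical-LASSO regularization, k-means clustering under
    city-block distance into recurring connectivity states, temporal state
    metrics (fractional windows, mean dwell time, number of transitions), and
    paired/between-group nonparametric statistics with covariate-adjusted
    Spearman correlations and FDR control. Includes a synthetic cohort
    generator with hidden semi-Markov connectivity states, a simplified group
    spatial ICA with back-reconstruction, head-motion quality control, and
    time-course postprocessing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    signal,
    nortest,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
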