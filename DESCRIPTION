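Package: ecgmcda
Title: Speedy ECG Classifier Selection by AHP-Based Multi-Criteria
    Decision Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to construct and select a binary cardiovascular-disease
    classifier from single-lead ECG segments. Implements a Pan-Tompkins-style
    preprocessing chain (bandpass, derivative, squaring, sliding-window
    integration) with Q/R/S fiducial detection, a 10-dimensional fiducial
    feature set (mean and standard deviation of Q, R, S amplitudes, QRS
    duration and RR interval), an exhaustive cross-validated sweep of a
    3rd-order polynomial-kernel support vector machine over all 1023
    feature subsets, and analytic-hierarchy-process (AHP) multi-criteria
    decision analysis over seven performance criteria (overall accuracy,
    sensitivity, specificity, AUC, training time, testing time, number of
    features) to pick the optimal configuration. A seeded disease-conditioned
    synthetic ECG generator and a synthetic pairwise-comparison survey
    generator make the whole pipeline runnable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
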