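Package: steroidratio
Title: Serum Steroid Ratio Profiling for Prostate Cancer Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds combinatorial concentration-ratio profiles from
    10-steroid serum panels and classifies subjects (prostate cancer,
    benign prostate hypertrophy, healthy control) by leave-one-out
    similarity matching with a Bayesian posterior and an iterative
    correction factor.  Includes single-marker baselines from
    geometric-mean confidence-interval thresholds (PSA, DHEAS), ROC/AUC
    evaluation, attribution of class-discriminating steroid ratios to
    steroidogenesis enzymes via a pathway graph, a seeded synthetic
    cohort generator, and calibration-curve quality-control utilities
    (LOD/LOQ, precision, accuracy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    pROC,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
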