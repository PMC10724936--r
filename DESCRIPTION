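Package: octffr
Title: Ensemble Assessment of Coronary Lesion Significance from OCT Lumen Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Reimplements a coronary-lesion significance pipeline built on
    optical coherence tomography (OCT) lumen radii profiles and invasive
    fractional flow reserve (FFR) ground truth: geometric feature extraction
    from 1-D radius signals, pressure-drift correction and FFR labeling,
    univariate base-learner ranking under grouped cross-validation,
    ROC-cutoff ensemble voting with log-odds weights, and diagnostic
    reporting with Wilson and Hanley-McNeil confidence intervals. Includes a
    calibrated synthetic cohort generator emulating the statistical
    structure of a single-center 80-patient / 102-lesion study so every
    stage is testable without private clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    randomForest,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
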