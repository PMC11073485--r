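Package: ifscreen
Title: Intrinsic Frequency Analysis of Carotid Pressure Waveforms and
    Decision-Tree Screening for Low Ejection Fraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts cardiovascular intrinsic frequencies from carotid
    pressure waveforms by fitting a piecewise two-sinusoid model to each
    cardiac cycle with an equality-constrained least-squares solver and a
    global grid search, derives heart-rate-normalized systolic indices, and
    screens for low left-ventricular ejection fraction (<50%) with published
    fixed decision rules and constrained CART classifiers evaluated by
    leave-one-out cross-validation with ROC analysis. Includes beat
    detection, dicrotic-notch estimation, cycle quality scoring, a seeded
    synthetic-cohort generator built on the exact forward model, and a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    rpart,
    optparse
Config/testthat/edition: 3
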