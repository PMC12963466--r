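Package: stonewindow
Title: Half-Value Window Measurement of Dense Objects in Non-Contrast CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reproducible size measurement of calcified objects
    (urinary stones) in non-contrast computed tomography. Implements the
    half-value window principle (window center at half the object-to-
    background attenuation difference, window width zero), a synthetic
    stone-phantom generator with Gaussian point-spread blur emulating
    blooming and partial-volume effects, a semi-automated measurement
    pipeline (histogram-circle ROI statistics, threshold segmentation,
    maximum Feret diameter over axial/coronal/sagittal reformations), a
    simulated multi-observer study, limits of agreement with the mean
    (LOAM) under an additive two-way random-effects model with
    modified-large-sample confidence intervals, and logistic prediction
    curves for spontaneous stone passage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    lme4,
    RNifti,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
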