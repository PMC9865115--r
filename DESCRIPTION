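Package: gaitplanes
Title: Body-Axis Plane Projection and Gait Index Analysis for Markerless
    Motion Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts full-body 3D keypoint time series, as exported by
    markerless smartphone motion-capture apps, into two-dimensional
    projections on sagittal, coronal, and axial planes anchored to the
    body axis (navel, shoulders, hips) rather than the ground. Fits
    bivariate-normal tolerance ellipses to the projected keypoint
    scatter, computes seven pathological-gait indices (hip and knee
    joint angle ranges, relative vertical heel amplitude, foot angle,
    and heel/toe/leg outward shifts) with published screening cutoffs,
    and evaluates cohort-level detectability via ROC AUC, sensitivity,
    specificity, and odds ratios. Includes an articulated kinematic gait
    simulator for normal, shuffling, short-stepped, and wide-based gait
    patterns walking a 1-m circle, emulating the app's CSV export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pROC,
    stats,
    tools,
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
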