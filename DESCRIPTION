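Package: segqc
Title: Unsupervised Quality Estimation for Segmentation Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quality control for ensembles of 3D medical image
    segmentations without ground truth. Candidate masks for each case are
    fused (equal-weight majority voting or SIMPLE iterative fusion), each
    candidate is scored against the fusion with volumetric Dice and
    anisotropic-spacing Hausdorff distance, and robust per-algorithm
    thresholds (median minus alpha times the median absolute deviation)
    raise alarm flags that accumulate into per-case risk scores for triage.
    Includes alpha-calibration diagnostics (alarm-count histograms, Shannon
    entropy, correlation with reference quality) and a seeded synthetic
    phantom-cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
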