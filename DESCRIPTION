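Package: storymvpa
Title: MVPA Decoding of Attention and Agent in Story-Based fMRI
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: End-to-end multivoxel pattern analysis (MVPA) pipeline for a
    story-reading fMRI paradigm with a 2 x 2 factorial design (attention
    type x agent) plus a nonsocial control: trialwise beta-series
    estimation by least-squares-all GLM, spherical MNI region-of-interest
    extraction, leave-one-run-out linear support vector machine decoding
    with fold-wise z-normalization, cross-classification and interaction
    difference scores, searchlight accuracy maps, group-level permutation
    inference with bootstrap confidence intervals and false discovery rate
    correction, and a gaze-grid eye-movement decoding control. Includes a
    synthetic-data generator (design, BOLD, eye samples, behavior) with
    known ground-truth effect structure so the whole pipeline is testable
    without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
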