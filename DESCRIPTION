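Package: physbold
Title: Physiological Coupling Analysis of the BOLD Signal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how peripheral physiology (cardiac rhythm,
    respiration, end-tidal CO2) propagates into resting-state BOLD fMRI.
    Preprocesses photoplethysmogram, respiration-belt and capnograph recordings
    into TR-locked heart-rate, respiratory-variation and end-tidal CO2
    timecourses with heart-rate-variability summaries; builds cardiac,
    respiratory and CO2 response-function regressors by convolution; fits
    voxelwise linear models and percent-variance-explained maps; computes
    lag-resolved cross-correlations between BOLD and physiological signals,
    voxelwise and per tissue compartment; and performs group comparisons with
    threshold-free cluster enhancement (TFCE) permutation correction. A
    synthetic-cohort generator with known ground truth makes every stage
    verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
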