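Package: vibeeg
Title: Removal of Whole-Body-Vibration Movement Artifacts from EEG with
    Acceleration-Referenced Adaptive Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for removing whole-body-vibration (WBV) movement
    artifacts from multichannel EEG recordings using adaptive noise
    cancellation (NLMS and RLS) referenced to a synchronized vertical
    head-acceleration trace. Includes a semi-synthetic contamination
    benchmark with SNR-calibrated mixtures, a seated-body resonance model
    for head acceleration, Welch power spectral density and
    magnitude-squared coherence estimation, temporal and spectral RRMSE
    and relative band-power metrics, a standard EEG preprocessing
    pipeline (trim, resample, detrend, common-average reference, FIR
    bandpass, bad-channel handling, variance-based epoch rejection), and
    vibration-stress indices (frontal alpha asymmetry and frontal
    relative band powers) with Friedman and Durbin-Conover rank
    statistics. Reads BrainVision and EDF recordings and round-trips a
    plain-text fixture format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
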