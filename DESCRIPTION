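Package: hemobeat
Title: Beat-by-Beat Estimation of Left-Ventricular Hemodynamics from Heart
    Sounds and Pulse Waves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates four left-ventricular hemodynamic parameters (systolic
    and diastolic pressure, and the maximum rates of pressure rise and
    decline) on a beat-by-beat basis from non-invasive phonocardiogram (PCG)
    and photoplethysmogram (PPG) signals. Provides zero-phase band-pass
    preprocessing of multichannel 1 kHz recordings, Pan-Tompkins R-wave
    detection and R-to-R cycle segmentation with signal-quality screening,
    reference-label extraction from intraventricular pressure with
    spike repair, a compiled one-dimensional residual convolutional network
    with a bidirectional GRU trained by mean-squared-error regression,
    record-level within- and cross-subject evaluation schemes with
    one-record calibration, and a physiologically coupled multichannel
    signal simulator for end-to-end validation without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
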