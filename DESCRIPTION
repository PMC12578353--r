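Package: critslow
Title: Critical Slowing Down in Random Recurrent Rate Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates sparse random recurrent firing-rate networks at
    controlled proximity to their critical point and provides the analysis
    machinery used to study amplification of ultra-slow cortical
    fluctuations by critical slowing down. Includes random-matrix
    diagnostics of the control parameter, synthesis of intracranial-EEG-like
    population signals by partial summation of unit activity, Welch spectra
    with Lorentzian and power-law fits, auto- versus cross-spectral
    calibration of the operating point, paired rest-versus-recall contrasts
    with signed-rank and false-discovery-rate statistics, robustness scans
    over network size, gain, input-noise spectrum and additive drive, and a
    surrogate generator that emulates the statistical structure of
    empirical high-frequency-broadband recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
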