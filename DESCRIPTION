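Package: radarvitals
Title: Contactless Breathing and Heart Rate Monitoring from FMCW Radar
    Sleep Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Processing pipeline for frequency-modulated continuous-wave
    (FMCW) radar recordings of sleeping subjects. Converts raw radar cubes
    (frame x chirp x range bin) to per-bin displacement time series via the
    chirp-median phase method, detects and excludes high-motion intervals
    with a Doppler-FFT motion parameter, selects the range bins carrying
    breathing and heartbeat motion either by temporal phase coherence
    ranking (single bin) or by persistence homology of the phase signal
    (multiple bins), estimates breathing rates by autocorrelation and heart
    rates by peak detection within physiological bounds, and evaluates
    agreement against reference polysomnography rates (MAE, MAPE, Spearman
    correlation, recall, uncovered duration, Bland-Altman limits). A bed
    scene simulator generates radar cubes with ground-truth rate tracks so
    the full pipeline can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
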