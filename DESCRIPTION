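Package: tcdenv
Title: Maximal Flow Velocity Envelope Tracing for Transcranial Doppler
    Spectrograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Calibration-free estimation of the maximal blood flow velocity
    waveform (the spectrogram envelope) from transcranial Doppler ultrasound.
    Computes time-velocity spectrograms from demodulated IQ echo signals,
    segments them with a grid of Otsu-derived intensity thresholds, traces the
    envelope under physiological edge-following constraints, and selects among
    candidate envelopes with a beat-by-beat signal quality index built from
    template matching. Includes the classical modified threshold crossing
    method as a baseline, agreement metrics against reference tracings, and a
    seeded synthetic Doppler scene generator with retained ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
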