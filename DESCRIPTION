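Package: pttkit
Title: Simulation and Analysis of Pulse Transit Time from Synchronized ECG/PPG Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for pulse transit time (PTT) studies with
    wearable-style hardware: simulate synchronized 1 kHz ECG and
    photoplethysmogram (PPG) recordings with fully known ground truth
    (beat times, per-beat PTT, noise components), store them in a compact
    device-style binary container with event markers, condition the signals
    (baseline removal, mains notch, normalization, artifact flagging),
    locate ECG R-peaks and PPG fiducial points, and derive per-beat PTT
    series, heart rate, heart-rate variability, vasoconstriction-response
    fits, and Moens-Korteweg pulse wave velocity estimates. Includes a
    hyperbaric oxygen therapy session-profile generator and a command-line
    interface for reproducible simulate/analyze/inspect runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
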