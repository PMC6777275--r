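Package: shiftpulse
Title: Pulse Rate Variability Analysis for Wearable Wrist PPG Shift Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing pulse rate variability (PRV) from wearable
    photoplethysmography (PPG) recordings collected over long work shifts.
    Provides strict readers and writers for vendor-style blood-volume-pulse
    (BVP) waveform and interbeat-interval (IBI) session exports, a synthetic
    session generator with exact ground truth (integral pulse frequency
    modulation beat process, configurable artifact dropout), a bandpass
    peak-picking beat detector with per-window signal-to-noise gating,
    inclusion screening for paired repeated-measures cohorts, time-domain
    (median pulse rate, mean R-R interval, SDNN, RMSSD) and frequency-domain
    (LF/HF band power of the cubic-spline RR tachogram via Welch's method)
    metrics, an interpretable-time yield quotient, and paired t-test cohort
    comparison with post-hoc power from the noncentral t distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
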