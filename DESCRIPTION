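Package: vitalpencil
Title: Vital-Sign Extraction from Microwave Radar Signals by the Matrix Pencil Method
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-contact monitoring of respiration and beat-to-beat heart rate
    from continuous-wave (CW) Doppler and ultra-wideband (UWB) impulse radar
    signals. The core estimator decomposes a sampled displacement signal into a
    sum of damped complex exponentials with the matrix pencil method (Hankel
    matrix, singular-value truncation, pencil eigenvalues, Vandermonde residues)
    and separates breathing, its harmonic family and the heartbeat by pole
    selection. Includes I/Q ellipse-fit imbalance correction and arctangent
    demodulation for CW sensors, radargram clutter removal, cross-correlation
    motion compensation and range-bin selection for UWB sensors, variational
    mode decomposition and band-pass filter baselines, peak-to-peak heart-rate
    variability scoring with Bland-Altman agreement statistics, and a seeded
    synthetic-data generator for both sensor types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
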