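Package: gaitsock
Title: Gait Event Detection from an Instrumented-Sock Strain Sensor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for detecting heel lift, toe off and heel strike from the
    voltage signal of a piezo-resistive textile strain sensor knitted into a
    sock.  Provides the signal-conditioning primitives used with such sensors
    (zero-phase FFT high-/band-pass filtering for baseline-drift removal,
    zero-lag Butterworth low-pass filtering, linear upsampling and
    peak-to-peak scaling), per-gait-cycle similarity statistics between the
    sensor and an ankle-angle kinematic signal (Pearson correlation and the
    normalised mean absolute deviation), a five-parameter peak-plus-offset
    event detector with automated per-subject calibration, a train/test
    evaluation protocol reporting errors in percent gait cycle, and a
    synthetic cohort generator that emulates the sensor's documented
    behaviour (drift, hysteresis-like asymmetry, trial-to-trial timing
    jitter and a shod-condition failure mode) with ground truth for every
    event.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
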