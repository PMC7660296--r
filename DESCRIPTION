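Package: fmsim
Title: Fetal Movement Simulator and Vibration-Sensor Evaluation Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An in-silico twin of a laboratory fetal-movement simulator for
    pre-clinical evaluation of wearable vibration sensors. Implements the
    closed-form vibration and biaxial prestress mechanics of a single-layer
    gravid-abdomen membrane model (curved design model and flat silicone
    testbed), synthesizes multi-sensor recordings (accelerometer, acoustic
    sensor, piezoelectric diaphragm) of simulated fetal kicks, and provides the
    accompanying signal-characterization pipeline: zero-phase Butterworth
    filtering, threshold-based kick detection, signal/noise energy and SNR
    estimation, Welch power spectral density, spectrogram, and dominant
    frequency mode. Experiment drivers reproduce displacement sweeps, distance
    sweeps, detection-threshold studies, and comparative sensor-response
    studies on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
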