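Package: penbeat
Title: Heart Rate Estimation from a Smart Pen's Built-In Accelerometer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts beat-to-beat heart rate from the triaxial accelerometer
    of a digital writing device. Implements the full processing chain --
    count-to-g rescaling, Euclidean magnitude fusion, zero-phase low-pass
    Butterworth filtering, ballistocardiographic beat-peak detection and
    RR-interval/heart-rate computation -- together with an ECG-anchored
    cutoff-frequency calibration loop and a method-agreement statistics
    battery (Pearson and cosine similarity of beat timestamps, mean squared
    error and Welch's t-test of inter-beat intervals, timestamp regression
    and distribution summaries). A synthetic-recording generator with known
    beat ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
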