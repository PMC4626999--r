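Package: ppgheat
Title: Heat-Stress Detection from Whole Photoplethysmogram Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting heat stress from short fingertip
    photoplethysmogram (PPG) recordings analysed as a whole, without
    beat-by-beat waveform delineation. Implements recursive first-difference
    derivative cascades of the raw and 0.5-7 Hz bandpass-filtered signal up
    to order 20, normalized energy and normalized Shannon entropy features of
    every derivative order, systolic peak detection and RMSSD heart rate
    variability, mass-univariate Mann-Whitney screening with Holm-Bonferroni
    correction, and leave-one-out benchmarking of Mahalanobis, LDA, QDA and
    linear SVM classifiers, including a combined entropy + RMSSD quadratic
    detector. A seeded synthetic cohort generator provides paired
    rest/heat-stress PPG recordings with configurable heart rate, RMSSD,
    pulse morphology and noise structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    e1071,
    signal,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
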