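Package: benthoforce
Title: Hydraulic Force Time-Series Analysis for Fixed Fish Bodies in a Flow Channel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the hydraulic forces experienced by fixed
    (preserved or printed) fish bodies in a laboratory flow channel. Converts
    raw three-channel sensor records (torque X/Y, force Z, 1000 Hz) into
    per-run force summaries via the moment-arm conversion, compares treatments
    with Kruskal-Wallis/Dunn nonparametric statistics and an inverse-Gaussian
    log-link GLM on morphometric predictors, characterises treatments by
    Welch power-spectral-density peak sets, and classifies treatment from the
    force time series with a four-block residual 1D convolutional neural
    network trained on smoothed, downsampled, segmented records. A seeded
    synthetic-data generator emulates the flume experiment (cohort
    morphometrics, calibrated mean forces, signal-to-noise ratios and planted
    spectral peaks) so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
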