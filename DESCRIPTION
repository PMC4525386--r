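Package: ramanfphw
Title: Dual-Range Fiber-Optic Raman Spectral Analysis for Esophageal
    Cancer Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of simultaneous fingerprint
    (800-1800 cm-1) and high-wavenumber (2800-3600 cm-1) fiber-optic
    Raman spectra of esophageal tissue for discriminating squamous cell
    carcinoma from normal mucosa. Provides a labelled synthetic cohort
    generator with ground truth, spectral preprocessing
    (Savitzky-Golay smoothing, polynomial autofluorescence baseline
    removal, combined-area normalization, signal-to-noise quality
    control), per-channel Student's t statistics with significant-region
    extraction, peak-intensity ratio classifiers, Cohen's kappa, and
    mean-centered PLS-DA (NIPALS) with leave-one-patient-out
    cross-validation, logistic posterior calibration, patient-level
    train/test splitting, confusion metrics and ROC analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    pROC,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
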