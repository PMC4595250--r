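Package: sersdx
Title: Serum SERS Diagnostic Workflow with Two-Step SVM Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for label-free serum surface-enhanced Raman spectroscopy
    (SERS) diagnostics. Provides readers and writers for two-column spectra
    with cohort manifests, a synthetic cohort simulator with patient-level
    random effects, a preprocessing chain (quality control, iterative
    polynomial autofluorescence baseline removal, Savitzky-Golay smoothing,
    normalization), group mean and difference-spectrum peak analysis with
    biochemical band assignment, and a two-step support vector machine
    diagnostic evaluated under leave-one-spectrum-out and
    leave-one-patient-out cross-validation with specificity, sensitivity,
    accuracy and Matthews correlation coefficient reporting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    pracma,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
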