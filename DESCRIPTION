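Package: diaforge
Title: Assay Library Construction, Peak Scoring and Differential
    Quantitation for Data-Independent Acquisition Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and refining targeted assay libraries for
    data-independent acquisition (DIA) mass spectrometry and for using them
    to quantify population-specific proteome signatures. Covers in-silico
    tryptic digestion and fragment mass computation, transition selection
    from spectral libraries, a seven-step library filter cascade with
    codified peak-curation rules, overlapping isolation-window schemes,
    targeted chromatogram extraction, indexed retention time (iRT)
    calibration, mProphet-style semi-supervised target-decoy peak scoring
    with q-value estimation, median-polish protein summarization,
    one-vs-rest differential abundance testing with Benjamini-Hochberg
    correction, power analysis for minimum detectable fold change, and
    cross-sampling reproducibility statistics. A seeded synthetic DIA
    simulator with full ground truth makes every pipeline stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
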