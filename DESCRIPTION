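Package: peakcal
Title: Supervised Calibration and Evaluation of ChIP-seq Peak Detectors
    from Visually Labeled Regions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for training and evaluating ChIP-seq peak detection
    models against visually determined region labels of four types
    (noPeaks, peaks, peakStart, peakEnd). Implements the annotated-region
    label error E = FP + FN, single-parameter grid-search calibration of a
    significance threshold, window-based K-fold cross-validation, ROC-like
    threshold sweeps and learning curves, plus a minimal thresholding peak
    caller and a synthetic labeled-benchmark generator with planted peaks
    shared within cell types, so the whole workflow is testable without
    external data. Readers and writers for the label dialect, BED3,
    narrowPeak, bedGraph coverage, threshold manifests and result tables
    are included, along with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
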