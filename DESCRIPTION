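Package: icpcell
Title: Quantitative Single-Cell Elemental Analysis by ICP-TOFMS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for absolute element quantification in single cells from
    inductively coupled plasma time-of-flight mass spectrometry (ICP-TOFMS)
    data. Detects transient cell events in time-resolved single-cell ICP-MS
    traces by iterative outlier thresholding over a Poisson instrument
    background and converts event intensities to femtogram masses via liquid
    standard calibration. Quantifies element content per cell from laser
    ablation (LA-ICP-TOFMS) multi-channel pixel maps using bright-field guided
    segmentation, segment transfer and integration, and gelatin microdroplet
    calibration, including per-cell limits of detection. Provides QC flagging
    (rhodium intercalator dead-cell marker, morphology filters), population
    statistics (quartile summaries, Welch tests, size normalisation), a
    synthetic-data generator with ground truth for end-to-end validation, and
    pipeline drivers with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    EBImage,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
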