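Package: ermorph
Title: Single-Cell Quantification of Endoplasmic Reticulum Remodeling in
    High-Content Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-analysis and screening-statistics pipeline for
    quantifying endoplasmic reticulum (ER) architecture in single cells from
    multi-channel fluorescence microscopy. Segments nuclei and cells, filters
    artifacts and out-of-focus objects, partitions each cytoplasm into
    perinuclear and peripheral bands at fixed proportional distances between
    the nuclear boundary and the cell edge, and computes the ER expansion
    ratio, ridge/hole texture scores, whole-cell shape features, protrusion
    polarity metrics, proximity-ligation spot counts, transwell and
    3D-invasion readouts, and plate-level control-referenced Z-score
    statistics with replicate t-tests and hierarchical clustering of
    condition profiles. Ships a synthetic field-image generator with
    exhaustive ground truth so the full pipeline is testable without
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
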