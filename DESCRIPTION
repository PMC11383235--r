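Package: replicascan
Title: Inter-Scan Variability of Nucleus Detections in Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how reproducibly a nucleus-detection pipeline behaves
    across technical replicate scans of the same histology slide. Reads
    per-nucleus measurement tables exported from segmentation tools, aligns
    replicate detections with an iterative median-shift (or affine)
    registration, matches nuclei between scans with a two-round
    conflict-resolving nearest-neighbour procedure that accounts for
    edged-out nuclei near the region border, and summarises agreement of
    per-nucleus measurements (area, median hematoxylin and eosin) with
    ratio-scale Bland-Altman limits of agreement (quantile based, back
    transformed to percentages) and bootstrap percentile confidence
    intervals. A synthetic replicate-scan generator with a hard-core point
    process, positional jitter, drop-out, spurious small detections and
    multiplicative measurement noise makes the whole pipeline testable
    without image data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
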