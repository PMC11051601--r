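Package: holotrackr
Title: 3D Localization and Tracking of Swimming Microbes from Inline
    Holographic Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing three-dimensional positions of
    swimming micro-organisms from inline digital holographic microscopy
    (DHM) video. Provides a synthetic hologram generator for point-like
    weak scatterers with run-and-tumble motion, median-image background
    normalization, angular-spectrum (Rayleigh-Sommerfeld) back-propagation
    with Gouy-phase-anomaly axial localization, a bounding-box-size to
    axial-depth heuristic calibration with fourth-order polynomial depth
    correction, a classical template-matching reference detector emitting
    darknet-style bounding boxes, optimal-assignment track linking, and
    object-detection evaluation metrics (IoU, precision, recall, mAP).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    tiff,
    clue,
    matrixStats,
    generics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
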