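Package: fibernuclei
Title: Tiled Detection, Fusion and Morphometry of Nuclei Deposits on
    Membrane-Lung Fibers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cell-nuclei deposits in fluorescence microscopy images
    of extracorporeal membrane oxygenation (ECMO) membrane-lung fibers. Slices
    full-scale images into overlapping tiles, fuses per-tile instance
    detections back into one coherent set of global nuclei (score filtering,
    non-maximum suppression, and non-maximum merging by intersection over
    smaller area), clusters nuclei with a graph rule combining mask overlap
    and an adaptive centre-distance threshold, and reports per-nucleus
    morphometrics (area, perimeter, eccentricity, intensity, local density,
    nearest-neighbour distance) together with per-cluster and per-image
    summaries. Includes COCO JSON annotation I/O, a synthetic DAPI-like scene
    generator with exact ground truth, a pluggable detector-backend interface
    with a reference thresholding detector, and evaluation statistics
    (per-tile count/area comparison, Mann-Whitney U, average precision at
    IoU 0.5, relative deviation from expert counts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    readr,
    generics,
    jsonlite,
    yaml,
    tiff,
    png,
    jpeg,
    igraph,
    pracma,
    EBImage,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
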