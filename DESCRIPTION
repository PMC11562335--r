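Package: berrymorph
Title: Postharvest Berry Morphometrics and Colorimetry from Stage Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: High-throughput phenotyping of separated fruit photographed on a
    uniform stage. Segments berries and circular scale markers by classical
    HSV thresholding, measures oriented-bounding-box length and width,
    stacked-cylinder volume, stacked-frustum surface area, ISO roundness and
    solidity from the segmentation mask, and computes border-eroded colour
    statistics in RGB, grayscale, HSV and CIELAB. Pixel metrics are calibrated
    to centimetres from circular markers of known diameter, berries are
    assigned grid positions, quality-control failures are flagged, and results
    are written as tidy per-berry tables, CSV files and annotated images.
    Includes a synthetic scene generator with exact ground truth and
    range-normalised mean-difference statistics for comparing measurement
    platforms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    rlang,
    stats,
    grDevices,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
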