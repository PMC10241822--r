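Package: osnc
Title: Optimized Small-Neighborhood Clustering for Grayscale Image Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segmentation of 8-bit grayscale images by optimized
    small-neighborhood clustering (OSNC): per-pixel attribute vectors are
    clustered by an epsilon-neighborhood chain-growth procedure with a
    weighted, range-normalized distance classifier; segmentation centers
    and thresholds are refined by alternating fuzzy-membership and center
    updates; the image resampling rate is chosen by a variable-step search
    bounded by relative histogram-entropy loss; and the number of segments
    is selected by a fuzzy-correlation validity function. Includes a
    seeded synthetic generator of defect scenes (bright convex objects
    with crack, stain and breakage defects on a uniform background) with
    ground-truth label masks, accuracy metrics for mask agreement, and a
    command-line interface for batch segmentation, suited to surface-defect
    inspection imagery such as food products on a conveyor belt.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    png,
    tiff,
    yaml,
    jsonlite
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
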