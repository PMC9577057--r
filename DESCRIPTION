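Package: wsisampler
Title: Attention-Guided Patch Sampling and Tumour-Stroma Ratio
    Estimation for Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sparse, attention-guided patch sampling for gigapixel
    whole-slide images (WSIs) in digital pathology. Implements coarse-grid
    quasi-random sampling, iterative densification around
    classifier-detected tumour, two-stage false-positive correction,
    DBSCAN-based region-of-interest (ROI) prediction with convex-hull
    outlines, uniform in-ROI fill, and tumour-stroma ratio (TSR)
    estimation by several sampling strategies, together with a dense
    tile-by-tile reference pipeline.  A synthetic virtual-slide generator
    with known ground truth and a confusion-matrix-simulated patch
    classifier make the whole pipeline testable without real slides or
    trained networks; real slides and classifiers can be plugged in
    through the same contracts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    mgcv,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
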