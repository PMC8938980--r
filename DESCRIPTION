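Package: atlasquant
Title: Flexible Atlas Registration and Multi-Region Quantification for 2-D Biological Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Registers named-polygon atlas plates to 2-D microscopy images and
    quantifies a binarized label of interest per anatomical region. Atlas
    plates are ImageJ ROI-set ZIP archives (one .roi polygon per region);
    registration is a global linear rescale followed by an optional
    control-point thin-plate-spline free-form deformation. Segmentation is
    intensity-range thresholding with connected-component size filtering, or
    validation of an externally binarized mask. Measurements per region are
    area, object count (centroid-in-region), object density, and label
    percent area. Includes the matching interrater-reliability procedures:
    combined-trace percent overlap, per-rater summed-area tables, and
    Krippendorff's interval alpha. A deterministic synthetic-data generator
    (plates, punctate blob images, fill-fraction masks, perturbed rater
    traces) makes the full pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
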