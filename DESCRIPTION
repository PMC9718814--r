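Package: rgbdsizer
Title: RGB-D Fruit Sizing, Image Tiling, and Size-Stratified Detection
    Evaluation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates physical fruit diameters from RGB-D orchard imagery
    by combining detector bounding boxes with aligned depth maps through the
    pinhole trigonometric-ratio model (extent_mm = extent_px * depth / focal).
    Provides score gating of detections, depth sampling at the box centre,
    long/short-axis diameter reports, corner-anchored and overlapping-grid
    image tiling with cross-tile non-maximum-suppression merging, COCO-style
    average precision with small/medium/large size stratification, caliper
    verification arithmetic (per-object error and error rate, class
    summaries, split bookkeeping), and a seeded synthetic RGB-D orchard
    scene generator with occlusion-aware ground truth and a weights-free
    colour-threshold baseline detector so the whole pipeline is testable
    without trained networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    xml2,
    yaml,
    digest,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
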