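# rgbdsizer

Estimating the physical size of fruit on the tree is a core task in orchard
phenotyping and yield forecasting. `rgbdsizer` implements the depth-based
sizing pipeline used with consumer RGB-D cameras (e.g. the Intel RealSense
D435i): an object detector proposes bounding boxes on the RGB image, the
aligned depth map supplies the range to each fruit, and the pinhole
trigonometric-ratio model converts pixel extents to millimetres:

```
horizontal = (right - left) / focal * depth
vertical   = (bottom - top) / focal * depth
long axis  = max(horizontal, vertical),  short axis = min(horizontal, vertical)
```

with `focal` the focal length in pixels and `depth` the range at the box
centre in mm. Around that core the package provides:

* **Detection post-processing** — score gating (default ≥ 0.75), central-window
  or edge-midpoint depth sampling (median of non-zero depths), CSV size
  reports.
* **Depth/RGB alignment** — nearest-neighbour field-of-view resampling between
  co-located pinhole frames (16-bit PNG depth in mm; 0 = invalid).
* **Image tiling** for small-object detection — the four corner-anchored crops
  as well as a full-coverage overlapping grid, ground-truth transfer into tile
  coordinates, and greedy NMS merging of cross-tile duplicates.
* **Size-stratified evaluation** — greedy IoU matching, precision–recall
  curves, COCO-style AP (101-point interpolation) at IoU 0.5/0.75, and
  per-class AP/detection rate with small < 22×22 px², medium 22×22–34×34,
  large > 34×34 strata (on ground-truth box area).
* **Caliper verification arithmetic** — per-object error `|measured −
  predicted|` and error rate `100·error/measured`, class averages (mean of
  per-object rates), detection rates, and split bookkeeping; two measured
  verification tables (indoor artificial tree, outdoor orchard) are bundled.
* **A synthetic RGB-D orchard generator** — seeded scenes of near-spherical
  fruits with occluders, depth noise/dropout, occlusion-aware ground truth,
  and a weights-free colour-threshold baseline detector, so the whole pipeline
  is testable end-to-end without trained networks or field data.

## Worked example

Render a synthetic scene, detect, size, and verify against the known
diameters:

```r
library(rgbdsizer)

spec  <- randomScene(nFruits = 30, diameterRange = c(32, 37),
                     depthRange = c(500, 900), seed = 7)
scene <- renderScene(spec)
det   <- baselineDetect(scene$rgb)
rep   <- sizeReport(det, scene$depth, spec@camera, scoreThreshold = 0.75)
head(rep[, c("object_id", "score", "depth_mm", "long_axis_mm", "short_axis_mm")], 3)
#>   object_id     score depth_mm long_axis_mm short_axis_mm
#> 1         1 0.8187831 875.5513     35.72034      35.65392
#> 2         2 0.8058712 659.0593     31.80800      31.68942
#> 3         3 0.8055556 659.9239     34.61563      33.84034

rec <- endToEndRecovery(spec)
mean(abs(rec$predicted_mm - rec$true_diameter_mm))
#> [1] 0.3393582
```

Every recovered long axis lies within one pixel-equivalent
(`depth/focal` ≈ 1.4 mm here) of the true diameter. The verification
arithmetic matches the bundled caliper tables:

```r
indoor <- verificationTable("indoor")
summarizeClass(indoor[indoor$size_class == "medium", ])
#>   n_detected n_total mean_measured_mm mean_predicted_mm mean_error_mm
#> 1         19      19            34.94             34.47          2.06
#>   mean_error_rate_pct detection_rate_pct
#> 1                 5.9                100
```

A shell interface wraps the same functions
(`inst/cli/rgbdsizer size|evaluate|tile|merge|simulate|verify ...`).

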