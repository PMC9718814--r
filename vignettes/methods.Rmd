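---
title: "Depth-based fruit sizing: model, evaluation protocol, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-based fruit sizing: model, evaluation protocol, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgbdsizer)
```

## The sizing model

A pinhole camera maps a physical extent $s$ (mm) at range $z$ (mm) to a pixel
extent $p = f\,s/z$, with $f$ the focal length expressed in pixels. The
package inverts this per detection box:

$$\text{horizontal} = \frac{x_{max}-x_{min}}{f_x}\,z, \qquad
  \text{vertical} = \frac{y_{max}-y_{min}}{f_y}\,z,$$

reporting the larger of the two as the long axis and the smaller as the short
axis — fruits are oval, and verification against caliper measurements uses
the long axis. The model's assumptions are worth stating plainly:

* **The box tightly bounds the visible fruit.** Occluded parts are simply
  lost; the model makes no attempt at amodal completion, so partially hidden
  fruits are systematically undersized.
* **One range per fruit.** The depth map is sampled near the box centre; a
  sphere's surface is nearer than its centre by one radius, and at large
  off-axis angles a sphere's silhouette is wider than $2 f r/z$. Both effects
  are real and are quantified (not corrected) by the synthetic generator's
  `perspective` mode, below.
* **Depth and RGB are pixel-aligned.** Alignment is handled first, see below.

### Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| score threshold | 0.75 | — | only high-confidence boxes are sized; the gate is **inclusive** (`score >= 0.75`) and exposed as an argument |
| depth window | 3 | px | median of non-zero depths in a 3×3 window rejects isolated dropouts without blending across edges |
| depth mode | `center` | — | `edges` instead averages the two vertical box-edge midpoints; see below |
| IoU thresholds | 0.5, 0.75 | — | standard localisation strictness levels for AP |
| size breaks | 22, 34 | px | class boundaries on equivalent-square side; areas 484 and 1156 px² |
| merge IoU | 0.5 | — | cross-tile duplicate suppression |
| GT-transfer fraction | 0.5 | — | mirrors the annotation rule that objects more than half hidden are not labelled |

### The depth-sampling ambiguity

Descriptions of this pipeline mention both "the depth of the central point"
and "the depth values of both ends of the detected box". These are different
estimators: on a convex fruit the centre sample reads the nearest surface
point, while edge samples read ranges closer to the fruit's equatorial
plane. Rather than guess, both are implemented (`mode = "center"`, the
default, and `mode = "edges"`), selected by one argument throughout the
stack. The residual ambiguity — whether $z$ in the model means surface range
or fruit-centre range — is a genuine property of the method, and the
generator's two projection modes exist precisely to separate it from
implementation error.

## Depth/RGB alignment

RGB and depth sensors on an RGB-D rig differ in resolution and field of view
(e.g. 1920×1080 at 69.4°×42.5° vs 1280×720 at 86°×57°). `alignDepthToRgb()`
models the two as **co-located pinholes**: each target pixel's viewing angle
is converted to a source pixel through the two focal lengths and principal
points, and filled by nearest-neighbour lookup. Two deliberate choices:

* **No stereo baseline or extrinsics.** Real rigs have a small baseline;
  registering it requires hardware-specific calibration that cannot be
  exercised or tested here. The pure-FOV model is this package's choice and
  is stated as such.
* **Never interpolate depth.** Bilinear interpolation across an object edge
  blends foreground and background ranges and corrupts sizing; resampling is
  nearest-neighbour, and out-of-FOV pixels become 0 (invalid), the same code
  used by 16-bit PNG depth files.

## Tiling

Small fruits occupy a few hundred pixels in a full frame, and detectors
struggle at that scale; cropping the image into tiles effectively magnifies
the objects. Two schemes are provided and deliberately kept distinct:

* `cornerTiles()` — exactly four tiles, one anchored at each image vertex.
  This reproduces the four-crop protocol verbatim. For tile sizes below half
  the image the four corner tiles *do not cover the centre*; the spec's
  `coverage` flag records this and a warning is raised rather than silently
  changing the protocol.
* `gridTiles()` — a row-major grid with configurable overlap, last row and
  column shifted inward, guaranteeing full coverage for any valid overlap.
  Choosing the overlap at least as large as the largest annotated object
  guarantees every ground-truth box fits whole in some tile.

Objects detected in two overlapping tiles appear as near-duplicates after
mapping back to the original frame. No published algorithm is attached to
this problem, so the package uses the field's standard remedy: greedy
score-ordered non-maximum suppression at IoU 0.5, ties broken by smaller
`x_min` then `y_min`. Ground-truth transfer into a tile clips boxes and
keeps them only when at least half their area survives, by analogy with the
50% occlusion annotation rule.

## Evaluation protocol

Matching is greedy: detections in descending score order claim the
still-unmatched ground truth of highest IoU at or above the threshold, each
ground truth at most once. Precision and recall are the cumulative
$TP/(TP+FP)$ and $TP/(TP+FN)$ over the score-ordered pool. AP defaults to
**COCO-style 101-point interpolation** (the mean of the precision envelope at
recall levels $0, 0.01, \dots, 1$); a continuous envelope integral
(`pascal_continuous`) is kept for sensitivity analysis. The tooling that
produced the published numbers this protocol models is not explicit about
its interpolation, so the COCO convention is the *default*, not an assertion
of fact.

Stratification follows COCO ignore semantics, keyed on ground-truth box
area: out-of-class ground truths can be matched but count for nothing;
unmatched detections whose own area lies outside the class are ignored
rather than counted as false positives. Boundary classes are assigned
medium-inclusively: 22×22 and 34×34 are both medium, since small is "less
than" the first break and large "larger than" the second. Per-class AP is
computed at IoU 0.5 only.

## Verification arithmetic

Per object, `error = |measured − predicted|` and
`rate = 100·error/measured`; class summaries are arithmetic means of the
per-object values. Two conventions matter:

* **Mean of rates, not ratio of means.** The average error rate is the mean
  of per-object rates; dividing the mean error by the mean measured diameter
  gives a different (usually smaller) number. A regression test guards the
  correct formula.
* **Rounding half away from zero at 2 decimals** for reported values, full
  precision internally. Printed tables round this way; the test tolerance of
  ±0.01 absorbs residual convention differences. (One bundled average row
  recomputes to 2.06 mm against a printed 2.05 mm — exactly the half-count
  discrepancy this tolerance exists for.)

Undetected objects carry no error and are excluded from error averages but
included in detection-rate denominators.

## The synthetic generator

No field RGB-D imagery is redistributable, so the generator stands in for
image acquisition. It emulates: near-spherical fruits of known diameter
(defaults 32–37 mm at 0.5–0.9 m, the indoor verification condition; 18–32 mm
is the outdoor range), cluttered non-green backgrounds, opaque occluders,
z-buffer occlusion with per-fruit visible fractions, the annotation rule
(`annotated = visible fraction > 0.5`), Gaussian depth noise and dropout,
and full determinism from a single seed (per-component substreams are
derived from it).

Two projection modes separate testing from model critique:

* `consistent` — flat disks of pixel radius $f r/z$ at uniform depth $z$.
  This is the exact inverse of the sizing model, so end-to-end recovery is
  guaranteed to within rasterisation (±1 px ≈ $z/f$ mm); tests assert that
  bound.
* `perspective` — physically exact ray–sphere silhouettes (pixel radius
  $f r/\sqrt{z^2-r^2}$, true per-pixel surface range). The sizing model's
  bias on such scenes (surface-vs-centre range, off-axis silhouette
  stretching) is *measured and reported* by tests, not asserted to any value.

The baseline detector is a colour-threshold/connected-components stand-in
for a trained CNN: hue-gated mask, components of ≥ 20 px, score = fill
ratio. A solid disk fills ≈ π/4 ≈ 0.785 of its box, so intact fruits tend to
pass the 0.75 gate while occlusion-clipped fragments fall below — a
deliberately simple score with roughly the right semantics. Rasterisation
makes it borderline: at some seeds an intact fruit's fill ratio lands just
under 0.75 and is gated out, which is honest behaviour, not a test fixture.

**What passing tests do and do not show.** The synthetic suite validates the
geometry, bookkeeping and inversion of the implementation under known truth.
It does not validate detector quality on real imagery, real sensor noise
spectra, leaf/branch biophysics, or the stereo-baseline misalignment the
co-located-pinhole model ignores; published detector APs and field
detection rates (67.19/81.58/90.91% by size class) require trained networks
and restricted farm data and are out of scope by design.

## Numerical and degenerate-input choices

* Coordinates are 0-based, continuous, half-open `[min, max)`; box width is
  `x_max − x_min` with no ±1. Pixel $(i,j)$ covers $[i,i+1)\times[j,j+1)$
  with centre at $i+0.5$.
* Invalid depth is 0 mm everywhere (sensor convention); medians ignore
  zeros; a box whose window holds only zeros yields an invalid estimate with
  a reason, never a number.
* Degenerate (zero-area) boxes are rejected at construction, not tolerated
  downstream; scoreless boxes cannot pass a score gate or NMS.
* Ties: matching breaks score ties by `x_min` and IoU ties by ground-truth
  index; NMS breaks score ties by `x_min` then `y_min`. All orderings are
  deterministic.
* `prCurve()` refuses `n_gt = 0` (undefined recall) instead of returning
  NaN.

## Problem sizes

The test suite renders scenes at 128×96 to 320×240 for speed and exercises
the stock 1280×720 sensor geometry in the acceptance-style checks (one
30-fruit full-resolution scene, 100 randomised evaluation instances,
50-box NMS oracle comparisons). These sizes were chosen to keep the suite
comfortably interactive while covering the same code paths as
full-resolution data.

## Known limitations

Lens distortion, stereo extrinsics, point clouds and live capture are out of
scope. The sizing model cannot recover occluded extent and inherits the
surface-vs-centre depth ambiguity described above. The corner-tiling
protocol is reproduced faithfully even where it under-covers the image;
`gridTiles()` is the practical alternative, not a silent replacement.
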