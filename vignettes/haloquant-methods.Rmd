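---
title: "Measuring phosphate-solubilization halos: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring phosphate-solubilization halos: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haloquant)
```

## The assay and its statistic

Phosphate-solubilizing bacteria are plated on opaque medium containing
insoluble phosphate. A solubilizing strain dissolves the precipitate around
its colony, producing a clear halo; the assay's readout is the
solubilization efficiency

$$E_f = \frac{A + B}{A},$$

with $A$ the colony measure and $B$ the halo measure in the same units.
Two conventions for $A$ and $B$ circulate in this literature and
`haloquant` implements both without declaring either canonical:

* **Diameter mode** (`mode = "diameter_cm"`): $A$ and $B$ are colony and
  halo diameters, the definition used with ruler measurements. For
  segmented regions the package uses the *equivalent circular diameter*
  $2\sqrt{\text{area}/\pi}$, since a segmented blob has no unique chord.
* **Area modes** (`mode = "area_px"`, `"area_cm2"`): $A$ and $B$ are
  region areas. Because $E_f$ is a ratio it is exactly scale invariant —
  `haloquant` guarantees (and tests) that pixel and cm² areas give
  identical $E_f$.

In every mode $B$ is the **total** solubilization region: the halo *and*
the colony it encloses (class `AS`), not the annulus alone. With that
convention area-mode $E_f = B/A + 1 \ge 2$ whenever a halo fully contains
its colony, while $E_f = 2$ means "no halo beyond the colony". The two
conventions are not interchangeable — a plate measured both ways will give
different numbers (e.g. diameters 1.6/2.8 cm give 2.75 while the same
plate's pixel areas give ≈2.9) — which is why `analyze_plate()` records
the mode and all intermediate quantities alongside the index.

## Calibration

Plates are photographed in standardized square frames whose width equals a
known dish diameter. The pixel→cm factor is the integer truncation

$$\text{px/cm} = \lfloor \text{width}_{px} / \text{diameter}_{cm} \rfloor,$$

so the default 1746 px / 11 cm frame gives 158 px/cm (the exact quotient is
158.73). Truncation to an integer is the package's deliberate convention —
it matches how the factor is reported in practice, and any sub-percent
calibration error it introduces cancels entirely in area-mode $E_f$.

## The synthetic plate generator

No public dataset of annotated solubilization plates exists, so the
package ships a seeded generator (`synth_config()`, `generate_plate()`)
that renders what the segmenter is designed for and nothing more:

* a square frame (default 1746 px ≙ 11 cm dish) with a dark background
  (intensity 0.05), a bright agar disk (0.45), per colony a brighter
  clearing disk (0.80) and a dark colony disk (0.15) — ordering
  colony < agar < halo, because the halo is a clearing in opaque medium
  while the colony is dense growth;
* an optional multiplicative left-to-right illumination gradient (slope
  ≤ 0.3) and additive Gaussian pixel noise (`noise_sd`, default 0.01 in
  intensity units), applied to the image *only* and clipped to $[0,1]$;
* exact ground truth: the noiseless rasterized disks, each `AS` mask being
  the total halo∪colony disk, plus the per-colony true $E_f$ computed on
  those masks. The default single colony (radius 65 px, halo 90 px)
  produces a colony of ≈13.3 thousand px, the magnitude typical of the
  assay at this calibration.

The real intensity statistics of plate photographs are not published, so
these levels are plausible stand-ins chosen once, not measurements. The
generator deliberately omits photorealism: condensation, reflections,
medium turbidity gradients, colony texture, ragged halo edges and
multi-dish frames are all absent. Tests passing on synthetic plates
therefore demonstrate that the geometry, bookkeeping and arithmetic of the
pipeline are correct, and that the reference segmenter solves the idealized
problem — they do not certify performance on laboratory imagery, which is
exactly why the package also imports predictions from externally trained
segmentation models rather than privileging its built-in segmenter.

## Geometry conventions

One membership rule is used everywhere, so synthesis, rasterization and
quantification can never disagree by construction:

* Pixels are addressed `[row, col]`, 0-based, origin top-left; pixel
  $(r, c)$ has its center at the continuous point $(x{=}c,\, y{=}r)$.
* A disk contains a pixel iff the distance from the pixel *center* to the
  disk center is $\le$ the radius (inclusive).
* Polygons are stored normalized to $[0,1]$ in $(x, y)$ order (the
  YOLO-seg dialect); normalized $x$ maps to pixel-plane
  $x \cdot (\text{cols}-1)$, the inverse of the pixel-center
  normalization used when tracing contours.
* Polygon rasterization is an even-odd scanline fill evaluated at pixel
  centers, with half-open edge handling in $y$ (an edge counts for a
  scanline $r$ iff $y_1 \le r < y_2$ or $y_2 \le r < y_1$) and inclusive
  fills in $x$, so centers lying exactly on a boundary are kept. A row
  with an odd crossing count (possible only for degenerate self-touching
  input) is skipped rather than guessed.
* Mask→polygon tracing pads the boundary contour half a pixel outward
  from the component centroid so that re-rasterization retains boundary
  pixels; the package tests a round-trip IoU ≥ 0.98 on disks. The padding
  is exact for convex blobs, which colonies and halos are to good
  approximation; strongly concave regions would be padded imperfectly.

Component labeling is 8-connected (diagonal pixels touch): 4-connected
labels are computed first, then labels meeting diagonally are united by
union–find, so the result is exact rather than approximated by dilation.
`analyze_plate()` reduces each mask to its largest component before
measuring — the assay quantifies one colony/halo pair, and detached
speckle should not inflate an area — with smaller fragments simply
excluded, and ties broken deterministically by scan order.

## The reference segmenter

`segment_reference()` is a classical stand-in for a trained
instance-segmentation model, so the whole pipeline runs and is testable
offline. It assumes a single standardized dish per frame and the intensity
ordering above: it locates the dish by Otsu thresholding against the frame
background (largest bright component, holes filled), splits the dish
interior into three intensity groups by 1-d k-means seeded at the 2%, 50%
and 98% intensity quantiles (seeded initialization keeps it
deterministic; a dish whose intensities collapse to fewer than three
distinct levels is reported as colony-free rather than guessed at), opens
both extreme-intensity masks with a disc brush (default diameter 7 px) to
remove speckle, and keeps colonies of at least `min_object_px` (default
50 px). Each colony is paired with the `AS` component containing its
centroid; the emitted `AS` region is the hole-filled union of that halo
component and the colony, so the total-region convention holds by
construction. Its confidences are fixed at 1.0 — the pipeline has no
probabilistic head — so the 0.30 confidence filter is a no-op for it and
meaningful only for imported model predictions. The filter's comparison is
inclusive (`>=`), and it is idempotent and monotone in the threshold.

On the generator's study conditions the package requires (and tests)
parameter recovery: $E_f$ within 5% of truth on a noiseless plate, and
per-class IoU ≥ 0.9 at `noise_sd = 0.02`. Overlapping halos from adjacent
colonies are resolved by the centroid-pairing rule — colonies sharing one
merged clearing receive the same total region — a documented convention,
not a claim about how a human annotator would label such plates.

## Evaluation protocol

Predictions are scored against ground truth per class at the object level:

* greedy one-to-one matching by descending IoU; a pair with IoU ≥ 0.5
  (default) is a true positive, unmatched predictions are false positives,
  unmatched truths false negatives. Greedy matching is the documented
  contract; on scenes of well-separated objects it coincides with the
  exhaustive maximum-cardinality assignment, which the tests verify by
  enumeration on scenes of up to four objects per class.
* true negatives in a two-class segmentation task have no intrinsic
  counting unit, so `match_and_count()` requires an explicit
  `negative_units` count of object-free evaluation units and reports
  `tn = max(0, negative_units − fp)`.
* **Truncation, not rounding**: reported precision, recall, F1 and
  accuracy are floored at two decimals (9/17 = 0.529 reports as 0.52,
  15/16 = 0.9375 as 0.93), and F1 is the harmonic mean of the *truncated*
  precision and recall, itself truncated. Both conventions are required to
  reproduce metric tables published under this protocol from their raw
  confusion counts; computing F1 from raw counts instead would shift
  values by about a point (e.g. 0.88 vs a reported 0.87). Truncation never
  increases a value and changes it by less than 0.01. Undefined metrics
  (no positive predictions, or no ground-truth positives) yield `NA` with
  a warning instead of a silent 0.

$E_f$, by contrast, is rounded half-up to two decimals — the convention
that reproduces reported indices such as 2.92 from 2.9184 — with a small
epsilon guard so that floating-point representations of exact ties (x.xx5)
cannot round down.

## Dataset split

`split_dataset()` shuffles with a seed and assigns
$\lfloor n \cdot \text{fraction} \rfloor$ items to training (default
0.75); the floor rule is the package's choice for non-divisible $n$, so 8
items give 6/2 and 10 give 7/3. Changing the seed permutes membership but
never the counts, and train/test always partition the input exactly.

## Problem sizes and determinism

Generation and segmentation of a full-size 1746 px plate take a few
seconds each in pure R; the test suite exercises the same code on 128–512
px plates (with disk radii scaled to match, e.g. r = 65/90 px on a 512 px
dish) plus one full-size generation, keeping the whole suite around ten
seconds while covering every code path. Every stochastic step — generator
noise, the dataset shuffle — consumes an explicit seed and restores the
session RNG state afterwards, so pipeline runs are bit-reproducible per
configuration and calling the package never perturbs a user's random
stream.

## Known limitations

* The built-in segmenter targets the standardized imaging geometry
  (single dish, three well-separated intensity modes); plates with strong
  vignetting, turbid media or overlapping dishes need an external model,
  imported via YOLO-seg or COCO files.
* Diameter mode measures equivalent circular diameters, not caliper
  chords; for irregular colonies the two differ, and manual diameter
  measurements should be compared against diameter mode only qualitatively.
* COCO import supports polygon segmentations only (no RLE).
* The confusion-count protocol scores object presence, not pixel overlap
  quality beyond the matching threshold; mAP and PR curves are out of
  scope.
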