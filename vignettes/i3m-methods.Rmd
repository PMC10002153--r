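---
title: "Measuring the third-molar maturity index from two-part segmentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the third-molar maturity index from two-part segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5, fig.height = 5)
library(i3m)
```

## The index and the decision problem

Forensic age estimation around the 18-year boundary commonly relies on the
maturation of the mandibular third molar as seen on a panoramic radiograph.
The third-molar maturity index is

$$ I_{3M} = \frac{a + b}{c}, $$

where $a$ and $b$ are the widths of the two open root apices (mesial and
distal) and $c$ is the tooth height. As the root apices close with age the
index decreases toward zero; the conventional cut-off classifies a subject
as adult (18 or older) when $I_{3M} < 0.08$ and as a minor otherwise. The
index is a ratio of lengths measured on the same image, so the pixel scale
of the crop cancels and no physical calibration is needed.

`i3m` automates the measurement given a *two-part instance segmentation* of
the mineralized tooth tissue on a 256×256 crop:

* the **coronal instance**: crown plus the outer root walls, and
* the **apical instance**: the central inter-radicular structure, an
  inverted-U band whose two lower tips are the inner sides of the two open
  apices.

Each root canal is then the radiolucent gap *between* the two instances,
open from below the crown down to its apex. This wiring is what makes the
apex widths measurable: every open apex is flanked by exactly one wall of
each instance, and the canal centerline is the line equidistant to the two
instances. When the apices close, the gap between the instances vanishes
and the two parts can no longer be told apart — such teeth are rejected
with a `ClosedApexError`, mirroring the usual exclusion of radiographs
without two open apices.

Where the masks come from is deliberately out of scope: the package
measures any mask pair, whether drawn by an expert (e.g. with the labelme
annotation tool, whose JSON dialect is read and written natively) or
inferred by a segmentation network behind the pluggable input contract.

## The two measurement engines

Both engines start from the same canonical pose: `align_vertical()` rotates
both masks, about the midpoint of their barycenters, by the angle that maps
the coronal-to-apical barycenter vector onto the downward vertical. The
rotation center is a package choice (it keeps both instances in frame
symmetrically); masks are resampled with nearest-neighbor lookup so they
stay binary, and a pair presented upside down comes out rotated by 180°, so
the crown-up convention is self-enforcing. $c$ is shared by both engines:
the difference between the lowest and highest occupied row of the aligned
mask union (a continuous max − min convention, consistent with the
Euclidean distances used for $a$ and $b$).

### Radii partition (TDA)

1. **Canal midlines.** Each image row is scanned for background gaps
   flanked on both sides by tooth pixels; gap midpoints are linked across
   rows into polylines (nearest-column linkage, up to 5 px of column jump
   and 3 rows of hiatus), and fragments whose ends align across a blocked
   stretch of up to 12 rows are re-joined — noise pixels bridging a canal
   interrupt the row gaps without closing the apex. End rows whose
   midpoint jumps sideways (the flank there is a wall corner, not the
   canal wall) are trimmed, and every midpoint is refined by a few Newton
   steps to the column truly equidistant to its left and right wall: the
   defining property of the canal centerline. A polyline is a root canal
   when its gap separates the two instances in the majority of its rows
   and it reaches within 8 rows of the apical instance's lowest row — a
   tolerance of the order of the wall thickness, so a wall tip truncated
   by segmentation noise does not masquerade as a closed apex, yet an
   order of magnitude smaller than any root length. Speckle can split one
   canal into several surviving polylines, so when more than two qualify,
   the two most apical ones with terminal columns more than 6 px apart are
   kept.
2. **Radii partition.** From every midline point, rays are cast at 1° steps
   over 360°; a ray stops at the first tooth pixel. Boundary pixels
   first-hit by some ray form the canal-facing (pulp–dentine) boundary of
   their instance; boundary pixels never hit form the outward-facing
   (tooth–environment) boundary.
3. **Apex extremities.** On each side of a midline, the wall extremity is
   the terminal point of the canal-facing boundary. It is localized
   sub-pixel: the canal-side edge column is regressed on the row over the
   last 10 rows of the wall (within 6 px of the wall pixel flanking the
   terminal gap, which keeps the search local to this apex) and
   extrapolated to the terminal row, plus a half-pixel shift toward the
   canal because the continuous edge lies half a pixel beyond the innermost
   sampled pixel center. Averaging some ten edge samples cancels most of
   the raster quantization that a single-pixel landmark would inherit.
4. $a$ (mesial, left) and $b$ (distal, right) are the Euclidean distances
   between the two extremities flanking each canal.

### Skeleton endpoints (TDA-DL)

The apical instance is band-shaped, so its medial axis is an inverted U
whose two ends sit at the apices. The default backend extracts it by
Zhang–Suen thinning; side spurs shorter than 5 px influence only endpoint
selection, while the reported polyline is the shortest skeleton path
between the chosen endpoints (one per side of the band's column median,
most apical first). Thinning retracts a band's axis by about half the band
width and carries a raster-parity bias, so each ending point is re-anchored
to the centroid of the band's local end cap (the most apical mask pixels
within 8 px of the tip) — a mirror-symmetric, mask-determined landmark.
Three interior control points at arc-length quartiles are reported for
overlays only. The coronal limit points are the lowest
coronal pixels on each side of the vertical line joining the barycenters
(ties broken toward the line), and $a$, $b$ are the left and right
coronal-to-apical endpoint distances. Because the skeleton ends at the
band's medial tip rather than at the wall corner, this construction
systematically reads slightly wider apices than the radii partition — a
known property of the landmark choice, visible in the cohort comparisons
below. A learned skeleton model can replace the thinning backend through
`skeleton_backend`: any function returning five ordered `(row, col)`
control points.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `threshold` | 0.08 | ratio | adult/minor cut-off; `i3m == threshold` classifies as minor (the conservative direction in a safeguarding context), and the value is exposed for population-specific recalibration |
| `angle_step` | 1 | degree | ray resolution of the radii partition; sub-pixel boundary effects stay inside the 2 px landmark tolerance |
| `max_radius` | 60 | px | ray reach; covers the apex region around every midline point at 256 px crop scale |
| `spur_min_px` | 5 | px | skeleton spur length treated as noise on 256 px crops |
| `link_tol`, `reach_tol` | 5, 8 | px | canal linkage and apex-reach tolerances of the midline scan |
| `clip_limit`, `tiles` | 2, 8×8 | — | CLAHE defaults, the common radiography setting; a 1×1 tile grid degenerates to plain global histogram equalization |
| `max_rotation_deg` | 15 | degree | augmentation rotation bound, an anatomically plausible crop-orientation range; flips are horizontal only |

Mask pairs inferred by a network may collide or carry speckle, so the
measurement entry points first keep connected components of at least 12 px
and strip any overlap between the instances (`prepare_mask_pair()`); holes
are never filled, since the canals must stay open.

## The phantom generator

No radiographic data ship with the package. Every pipeline stage is instead
validated on `generate_phantom()`: a stylized two-rooted third molar built
from continuous polygon geometry with analytic ground truth — an elliptical
crown over two outer walls (coronal instance) and a central inverted-U band
(apical instance), with the two canals converging from a configurable top
width to the target apex widths. All landmarks (wall tips, band-tip medial
points, top/bottom extremes, canal centerlines) are stored in continuous
coordinates; in-plane rotation is applied to the *geometry* before
rasterization, so a rotated phantom is rendered exactly rather than
resampled, and recomputing distances between stored landmarks reproduces
the nominal $a$, $b$, $c$ to numerical precision at any rotation.

The default cohort conditions are apex widths $a, b \in [6, 20]$ px, tooth
heights $c \in [120, 200]$ px and rotations within ±20° on a 256 px grid —
a realistic range for third-molar crops at this resolution, with wall
thickness 6 px, crown height 0.30 c and gray-level noise of SD 0.03 on the
[0, 1] scale. `degrade_mask()` emulates segmentation error (seeded boundary
erosion/dilation patches plus sparse speckle, monotone in a severity
parameter), and `calibrate_degrade_severity()` bisects the severity to a
target mean IoU so that decision robustness can be studied at a chosen
segmentation quality — e.g. the IoU ≈ 0.9 regime of a well-trained network.

What the phantoms do *not* emulate: real crown and root morphology
(cusps, curved or convergent roots, superimposed anatomy), intensity
texture, partially erupted or angulated teeth, and true closed-apex
anatomy. Passing the cohort checks therefore demonstrates the geometric
correctness and noise robustness of the measurement chain, not clinical
performance on radiographs; the latter requires expert-annotated data fed
through the same interfaces.

```{r phantom, eval = FALSE}
ph <- generate_phantom(phantom_spec(a_px = 10, b_px = 12, c_px = 150,
                                    rotation_deg = 15, seed = 7))
autoplot(ph)
res <- measure_masks(ph$apical_mask, ph$coronal_mask, method = "both")
tidy(res$tda)
```

## Numerical choices and degenerate inputs

* **Pixel convention.** `(row, col)`, origin top-left, row increasing
  downward; the center of pixel $(i, j)$ is $(i, j)$ (1-based). "Lowest"
  always means largest row.
* **Rasterization.** A pixel belongs to a polygon iff its center lies
  inside under the even-odd rule; boundary centers count as inside.
  Zero-area polygons are rejected, polygons lying between pixel centers
  rasterize to an empty mask.
* **Resampling.** Nearest-neighbor for masks (labels stay binary),
  bilinear for gray images; content rotated out of frame is dropped.
* **Ties.** Coronal limit points break row ties toward the vertical axis;
  skeleton endpoint ties prefer the outermost tip; mesial/distal are
  assigned left/right in image coordinates — since the index uses $a + b$,
  a side swap cannot change the score.
* **Degenerate inputs.** Empty masks, overlapping or barycenter-coincident
  pairs, canal-less (closed-apex) geometries, bands without two skeleton
  tips, walls without an outward boundary, constant series in the
  statistics, and non-binary decision labels each raise a dedicated
  condition class rather than returning half-meaningful numbers.
* **McNemar variant.** With fewer than 25 discordant pairs the exact
  two-sided binomial p-value is reported (standard at a few dozen teeth);
  from 25 on, the 1-df chi-square without continuity correction. Both
  paths are exposed through `exact_threshold`.
* **Dispersion.** All reported SDs use the sample ($n-1$) denominator.

## Validation problem sizes

The shipped validation suite runs entirely on generated data: statistics
against closed-form and numerically integrated oracles (100 random samples),
IoU against brute-force set computation (1,000 random 32×32 mask pairs),
midline equidistance on 50 phantoms, parameter recovery, decision fidelity
and cross-engine concordance on a seeded 100-phantom cohort, and the same
cohort re-measured under degradation calibrated to mean overall IoU ≈ 0.9.
`scripts/acceptance.R` recomputes all cohort-level quantities from scratch
for any seed.

## Known limitations

* Exactly two roots/apices are assumed; three-rooted or single-rooted
  morphologies are out of scope, as are maxillary molars.
* The engines measure the apical foramen rather than the apical
  constriction, so both overestimate expert-style apex widths slightly —
  TDA-DL more so, by construction of its skeleton endpoint.
* Measurements inherit the quality of the segmentation: at mean IoU well
  below 0.9 the canal scan increasingly rejects teeth as closed.
* The 0.08 cut-off is population-calibrated; the default is the
  conventional value and should be re-derived for new populations.
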