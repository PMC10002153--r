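# i3m — automated third-molar maturity index measurement

Forensic odontologists estimate whether a person is a minor (< 18 years)
from the maturation of the mandibular third molar on a panoramic
radiograph. The standard quantity is the **third-molar maturity index**

```
I3M = (a + b) / c
```

where `a` and `b` are the widths of the two open root apices (mesial and
distal) and `c` is the tooth height; the index shrinks toward 0 as the
apices close with age, and `I3M < 0.08` is the conventional adult cut-off.
Measuring it by hand requires an experienced examiner; `i3m` automates the
measurement from a **two-part instance segmentation** of the tooth on a
256×256 crop — a coronal mask (crown + outer root walls) and an apical mask
(the central inverted-U band between the two canals) — however those masks
were obtained: expert polygon annotations in the labelme JSON dialect, or a
segmentation network plugged in behind the same mask-pair contract.

Two measurement engines are provided, both operating on the vertically
aligned mask pair (barycenter axis mapped to the downward vertical):

* **TDA** (radii partition): row-scan detection of the two root-canal
  midlines — the lines equidistant to the two instances — then rays cast
  from every midline point partition each instance boundary into a
  canal-facing and an outward-facing part; each apex width is the distance
  between the two wall extremities (the terminal points of the canal-facing
  boundaries) flanking that canal, localized sub-pixel by edge regression.
* **TDA-DL** (skeleton endpoints): the apical band's medial axis is an
  inverted U whose two ends sit at the apices; `a`/`b` are the distances
  from the lowest coronal point on each side of the barycenter axis to the
  skeleton endpoint on that side. The default skeleton backend is
  deterministic thinning; a learned model returning five control points
  can be substituted.

Around the engines the package provides the 0.08 decision rule, labelme
and PNG/CSV I/O, CLAHE preprocessing, seeded rotation/flip augmentation,
IoU segmentation evaluation with TP/FP/FN confusion overlays, an agreement
statistics battery (MAE ± SD, Pearson, paired t, McNemar), a synthetic
tooth-phantom generator with analytic ground truth, ggplot2 `autoplot()`
methods, broom-style `tidy()`/`glance()`, and a CLI
(`inst/cli/i3m`: `measure`, `evaluate-seg`, `compare`, `synth`,
`preprocess`).

## Worked example

Phantoms stand in for radiographs and come with analytic ground truth:

```r
library(i3m)

ph <- generate_phantom(phantom_spec(a_px = 10, b_px = 12, c_px = 150,
                                    rotation_deg = 15, seed = 7))
res <- measure_masks(ph$apical_mask, ph$coronal_mask, method = "both")
res$tda
#> <i3m_result TDA> I3M = 0.1518 (threshold 0.080) -> minor
tidy(res$tda)
#> # A tibble: 1 × 7
#>   method  a_px  b_px  c_px   i3m threshold decision
#> 1 TDA     9.91  12.9    150 0.152      0.08 minor
```

The engine recovers the nominal widths (10, 12 px) within a pixel after
undoing the 15° rotation internally, and the decision matches the ground
truth (`compute_i3m(ph$truth)` = 0.1467, a minor). On a 20-phantom cohort
the full comparison battery against the analytic truth reads:

```r
co  <- generate_cohort(20, seed = 1)
tab <- measure_cohort(co, "tda")
compare_scores(tab$i3m, tab$truth_i3m)
#> <i3m_comparison> n = 20
#>   MAE +/- SD : 0.0025 +/- 0.0021
#>   Pearson r  : 0.9973 (p = 6.3e-22)
#>   paired t   : 1.362 (p = 0.189, alpha = 0.01)
#>   McNemar    : 0.000 (p = 1, exact-binomial)
#>   agreement  : 100.0%
```

i.e. a mean absolute I3M error of 0.003 and full minor/adult agreement on
pristine masks. `autoplot(res$tda, apical = ph$apical_mask, coronal =
ph$coronal_mask)` draws the masks, landmarks and the a/b/c segments so any
score can be visually audited; see the methods vignette
(`vignettes/i3m-methods.Rmd`) for the model, parameter and validation
details.

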