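---
title: "Pectoral muscle removal: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pectoral muscle removal: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pectseg)
```

## The problem and the model

An MLO-view mammogram images the breast at roughly 45°, which unavoidably
includes part of the pectoral muscle: a bright, approximately wedge-shaped
region anchored in the chest-wall corner. `pectseg` removes it by exploiting
two regularities: the muscle is *brighter* than the surrounding breast
tissue, and its inferior margin is a *smooth, nearly monotone* curve when
parameterized as a column position per image row.

The pipeline is intensity thresholding → edge detection → 1-D curve fitting:

1. Two-stage global binarization (Otsu): tissue-vs-background, then
   bright-vs-rest restricted to foreground intensities. The bright
   4-connected component touching the chest-wall corner becomes the
   pectoral candidate. Using the within-foreground histogram for the second
   threshold matters: background pixels dominate a mammogram and would
   otherwise drag the threshold down into the breast-tissue range.
2. Canny edge detection on the binarized composite (background 0,
   foreground 0.5, bright 1.0). Running on the composite rather than the
   grayscale image makes the edge response a function of the *segmentation*
   rather than of texture; a `canny_input = "grayscale"` switch is kept for
   comparison.
3. Per-row boundary extraction along the candidate perimeter, with a jump
   guard (3% of the working width) that marks rows corrupted by
   dense-tissue bridges as missing.
4. Robust penalized least-squares interpolation of the curve (below), then
   rasterization back at native resolution.

Because the pipeline detects the breast/pectoral interface, the pectoral
mask and the breast mask are complementary by construction: they partition
the foreground exactly, a property asserted on every run of the test suite.

## The robust smoother

The boundary curve `y` (one column per row, `NA` where unobserved) is
fitted by the discrete Whittaker smoother

$$\min_z \sum_i w_i (z_i - y_i)^2 + s \sum_i (z_{i+1} - 2z_i + z_{i-1})^2 .$$

Design choices, in order of consequence:

* **Second-difference penalty.** Its null space is exactly the straight
  lines, and pectoral margins are near-linear; the fit therefore
  extrapolates sensibly across missing spans and reproduces a clean linear
  margin without bias. Both properties are tested to machine precision.
  Internally the fit is computed after removing the weighted least-squares
  line (a mathematical no-op, since lines are in the penalty null space)
  so that the sparse system stays well-scaled even for very large `s`.
* **Zero weights, not deletion, for missing rows.** The fitted value is
  then defined on *every* row — this is the interpolation that bridges
  edge-break bands.
* **`s` by generalized cross-validation**, minimized over a 30-point log
  grid on [1e-3, 1e6]. GCV(s) = n·RSS/(n − tr H)² with the hat trace
  computed exactly from the sparse penalized system. The grid is wide
  enough that the selected `s` is interior in all phantom experiments.
* **Bisquare re-weighting** (cutoff 4.685 robust-sd units, MAD scale,
  3 rounds, convergence tolerance 1e-6 on the relative change of the fit).
  This is what discounts rows whose observed edge was displaced a few
  pixels by a contrast break but not enough to trip the jump guard. `s` is
  selected once, before re-weighting, and held fixed: re-selecting per
  round couples the scale estimate to the smoothing level and was not
  needed at the error levels observed.
* The smoother contains no randomness.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `working_width` | 512 | columns | Full-resolution mammograms (≈2560 columns) carry no extra information for a global boundary; processing at 512 and upscaling the *curve* (not the mask) keeps runtime flat across vendors. 0 disables. |
| `canny$sigma` | 2 | px at working width | Suppresses noise while keeping the step edge of the binarized composite sharp. |
| `canny$high_quantile` | 0.90 | quantile | Strong threshold adapts to gradient content; on a binarized composite the edge pixels are far into the tail, so the choice is uncritical. |
| `canny$low_fraction` | 0.40 | — | Classical 2–3:1 high:low hysteresis ratio. |
| `jump_limit_frac` | 0.03 | fraction of width | Boundary slope between adjacent rows is far below 3% of the image width; larger jumps indicate bridged dense tissue. |
| `min_pectoral_rows` | 10 | rows | Below this support the structure is treated as absent rather than fitted. |
| `smoother$tuning_const` | 4.685 | robust sd | Standard bisquare constant (95% Gaussian efficiency). |

## The phantom generator

Phantoms are what every quantitative claim in the test suite is measured
on, so their construction is part of the method. A phantom is a half-
ellipse breast against the chest-wall edge with a pectoral wedge whose
boundary is `c(r) = top_column (1 − r/exit_row) + curvature (r/exit_row)(1 − r/exit_row)`,
rasterized with the same half-up rounding rule as the pipeline — so the
truth mask and a perfect prediction agree bit-exactly, and the wedge area
has the closed form `top_column·exit_row/2 + curvature·exit_row/6` used as
an independent check. Intensities default to background 0.02, breast 0.45,
pectoral 0.85; noise is additive Gaussian, clipped to [0, 1].

Default size is 416 × 320 — 1/8 linear scale of a 3328 × 2560
for-presentation mammogram — which keeps a 100-phantom experiment under two
minutes while leaving the wedge hundreds of rows tall; a full-size phantom
runs through the same code path unchanged. Two failure modes are modeled
explicitly because they are what the robust smoother exists to fix:
*edge breaks* (bands of rows where a 5-pixel strip on the pectoral side of
the boundary is reset to breast intensity, erasing local contrast) and
*dense-blob bridges* (bright bumps abutting the wedge that pull the
candidate perimeter outward, tripping the jump guard and producing missing
rows). Cohort draws can inflate right-side wedge areas (default ratio
1.10) to emulate the left/right asymmetry reported in screening cohorts.

What phantoms do *not* model: anatomical texture, the nipple and skin
line, scattered-radiation gradients, compression-paddle artifacts, or
genuinely curved/obscured muscle margins. Passing the phantom suite
therefore demonstrates correctness of the algorithmic chain under its
stated assumptions (bright muscle, smooth near-monotone margin), not
clinical-grade accuracy on real mammograms.

## Evaluation conventions

FP% and FN% are both normalized by the **true** pectoral area, so FP% is
unbounded above while FN% ≤ 100; the per-image mean error is (FP%+FN%)/2
and cohort summaries average per-image values. A published error table
whose Left block is exactly consistent with this definition pins it; its
Right/Both mean entries are not reproducible from their own printed FP/FN
parts under any simple pooling, a discrepancy we record rather than
reverse-engineer. The two-sample Z test uses unbiased variances and a
normal reference; the area comparison uses Welch's t with
Welch–Satterthwaite degrees of freedom, as the unequal-variance default.
No multiple-testing correction is applied: the comparisons are single and
planned.

## Numerical and degenerate-input conventions

* Intensities are min–max normalized per image; a constant image becomes
  all zeros, is flagged degenerate, and is rejected by the segmenter.
* Orientation: images are flipped so the chest wall is at column 1, using
  recorded metadata when present and the brighter column border otherwise;
  borders within 5% relative difference with unknown laterality trigger an
  `ambiguous_orientation` warning and no flip. Masks are flipped back to
  the acquisition frame on output, which makes segmentation exactly
  equivariant under mirroring.
* Non-maximum suppression breaks ties asymmetrically (`≥` toward the
  positive direction, `>` toward the negative), so plateau edges stay one
  pixel thin — an invariant the suite checks on seeded noise images.
* Rasterization uses the strict inequality `column < boundary` with the
  boundary rounded half-up, making mask areas bit-reproducible.
* `s = 0` with any zero weight would make the penalized system singular
  and is rejected; the GCV score returns `+Inf` at the interpolation limit
  `tr H ≥ n`.
* CLI batch runs never abort on a single bad image: failures are logged to
  that image's JSON diagnostics and the run continues.

## Problem sizes in the shipped experiments

The test suite and `scripts/acceptance.R` use 50-phantom cohorts per
condition (416 × 320), 25 mirrored pairs for the equivariance check, 100
random instances for the smoother-vs-dense-solve oracle, and 1,000
replicates for the Z-test level simulation — sizes at which every Monte
Carlo margin in the assertions is comfortable while a full run stays in
the minutes range on one CPU.

## Known limitations

* A muscle margin that is strongly curved, partially obscured, or broken
  for most of its length degrades the boundary support; below
  `min_pectoral_rows` observed rows the image is flagged
  `no_pectoral_found` rather than fitted.
* The brightness assumption fails on for-processing (raw) images with
  unusual windowing; inputs are expected to be for-presentation.
* Only single-frame 2-D mammograms are supported — no tomosynthesis.
* The DICOM reader is deliberately minimal (uncompressed little-endian,
  single frame, grayscale); anything else should be converted upstream.
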