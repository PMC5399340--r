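---
title: "Tracking tendon motion with optical-flow-guided multi-kernel block matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking tendon motion with optical-flow-guided multi-kernel block matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tendontrack)
```

## The tracking problem

Musculoskeletal ultrasound shows tendons as speckle-textured bands that
slide mostly parallel to the probe during joint motion. Quantifying that
sliding means following a rectangular region of interest through a noisy
B-mode video. Two classical tools sit at opposite ends of a trade-off:

* **Windowed Lucas–Kanade optical flow** linearizes brightness constancy
  (`Ix*Vx + Iy*Vy = -It`, solved by least squares over a window) and is
  accurate for *small* frame-to-frame motion, but it systematically
  underestimates larger displacements and its per-frame errors accumulate
  when estimates are chained.
* **Block matching** locates a reference patch in a later frame by
  exhaustive search, so it is immune to drift over long intervals, but
  with integer displacements it cannot see *sub-pixel* motion at all:
  matching every adjacent pair of a slowly moving sequence keeps rounding
  the true displacement to zero while the template is re-extracted, and
  the motion is simply lost.

`tendontrack` implements a combined tracker. Optical flow measures the
region displacement of every adjacent frame pair and accumulates the
signed horizontal component `Da`. When `|Da|` first reaches a threshold
`lambda_px`, the elapsed frames form a *flow period*: the period's
endpoint frames — far enough apart that the displacement is well above
the integer matching floor — are matched by multi-kernel block matching
(MKBM), and the per-frame displacements inside the period are
re-distributed along the optical-flow trend:

    d(t + i) = d_MKBM(t) + (d_OF(t+i) - d_OF(t)) *
               (d_MKBM(t+n) - d_MKBM(t)) / (d_OF(t+n) - d_OF(t))

so both endpoints equal the matched values exactly, while interior frames
inherit the *shape* of the flow estimate with its scale corrected by the
drift-free match. The region and template then move to the matched
position and the process repeats. If the flow trend is degenerate (zero
net flow over a period), interpolation falls back to linear in frame
index and the period is flagged.

## From 559 flow vectors to one region displacement

Flow is computed on a grid inside the region (defaults: a 101 x 41 px
region, a 17 x 17 window, 2-px grid step, giving 43 x 13 = 559 points,
each valid only where the 2 x 2 normal matrix is well conditioned).
Individual vectors are noisy; the reduction to a single region
displacement deliberately mimics how a sonographer would discount
outliers:

1. points vote by horizontal direction (`left` / `right`; exact zeros are
   ignored) and only the majority class is retained — voting ties fall
   back to the previous pair's direction;
2. `Va`, the mean |vx| of the top 5% of retained points, indexes how fast
   the region is moving;
3. a calibration table maps `Va` to a percentage `N`, and the region
   displacement is the mean of the top `N`% of retained points ranked by
   |vx|.

The `Va -> N` table exists because the two failure modes pull in opposite
directions: at speeds approaching the window scale the estimator
*underestimates*, so only the fastest points are trustworthy (small `N`);
at sub-pixel speeds the ranking itself selects noise, so a broad average
is needed (large `N`). The shipped default table
(`va_n_table()`: 0.5→60, 1.0→35, 1.5→20, 2.0→10, ≥3.0→5) is a monotone
placeholder anchored at the worked point `Va = 1.5 px -> N = 20%`; it
should be recalibrated for any particular imaging setup. Two calibrators
are provided: `calibrate_va_n()` consumes frame pairs with known
displacement (e.g. manual tracking), finding per pair the smallest `N`
whose top-`N`% mean matches the truth within 0.05 px and fitting monotone
piecewise-linear knots over binned `Va`; `calibrate_va_n_sim()` drives it
with simulated constant-velocity speckle at specified noise and
decorrelation levels.

Numerical notes: frames are pre-smoothed with a sigma = 1 px Gaussian;
spatial gradients are central differences of the smoothed *first* frame
and the temporal gradient is a forward difference. Anchoring the
gradients at frame `t` keeps the estimator in the classical mild
*underestimation* regime for larger motions — the behaviour the adaptive
frame-interval logic is designed around. (Averaging the two frames'
gradients instead would flip the bias to overestimation.) A point is
invalid when the smallest eigenvalue of its normal matrix is below 1e-6
of the largest. Top-k counts use ceilings and are at least 1.

## Multi-kernel block matching

The reference block is split 2 x 2 into four sub-blocks overlapping by 10
px in each dimension (left/top sub-blocks take the extra pixel for odd
sizes; 101 x 41 splits into 56/55 x 26/25). Each sub-block is matched
independently by exhaustive search over integer displacements in
`predicted ± search_range`, minimizing the mean sum of absolute
differences `SAD = sum(|T - R|) / (M*N)`; ties are broken toward the
smallest displacement magnitude. Using four kernels instead of one makes
the match robust to local speckle variation, and fusing by the *maximum
absolute horizontal displacement* rejects sub-blocks that straddle soft
tissue passively dragged along with less displacement than the tendon.
Fusion compares the integer search minima (ties: lower SAD, then lower
sub-block index); selecting on magnitudes rather than signed values keeps
the rule symmetric for leftward motion, and both modes are exposed
(`fusion = "magnitude"` / `"signed"`, plus `"ncc"` for the original
NCC-weighted-average multi-kernel fusion, used by the per-frame
comparator baseline).

Matching is integer-valued by default. An optional refinement
(`refine_subpixel = TRUE`) interpolates the SAD minimum with the
equiangular (V-shaped) three-point fit, which is exact for an ideally
translated block under SAD; it is applied to the *selected* sub-block
after fusion. Selecting on continuous refined values instead would bias
the fused displacement outward (the maximum of four noisy estimates
overshoots their common truth), which is measurable as a systematic
overestimate on constant-velocity sequences.

## Choosing `lambda_px` and the search range

`lambda_px` (default 10 px) balances two errors. Too small, and the
tracker degenerates toward per-frame matching with its quantization
floor; too large, and the period outlives the *decorrelation time* of the
speckle — out-of-plane motion gradually replaces the texture, the true
SAD minimum fades, and far-away spurious minima win. The default suits
tendon motion of roughly 1–3 px/frame, where periods last 4–13 frames.
For much slower motion the threshold should shrink proportionally:
`slow_motion_config()` packages the settings used for the phantom-sweep
studies (0.33 px/frame): `lambda_px = 3`, search range ±6 x ±4 px around
the flow prediction (the prediction is good to 1–2 px, so a wider window
only adds spurious candidates), sub-pixel refinement on, and a
regime-calibrated `Va -> N` table.

## The synthetic speckle phantom

Because raw ultrasound video of calibrated motion is not shippable, every
quantitative claim is exercised on a simulator
(`phantom_spec()` / `render_sequence()`): point scatterers with
continuous coordinates and exponential amplitudes are splatted bilinearly
onto the grid, shifted per frame by the ground-truth profile (sub-pixel
motion included), and blurred with an anisotropic Gaussian point-spread
function (sigma 2 px laterally, 1 px axially — lateral resolution is
coarser, as in B-mode). Frames share one global intensity scale (the
99.5th percentile of frame 0 maps to 0.85, approximating how B-mode video
fills its dynamic range) and receive additive Gaussian noise
(sigma = 0.02). Out-of-plane decorrelation is approximated by resampling
a fraction `rho` of scatterers every frame; adjacent-frame correlation is
then `(1 - rho)` and texture memory decays geometrically.

What the simulator does *not* model: RF beamforming and Rayleigh
amplitude statistics, depth-dependent resolution, shadowing, tissue
deformation within the region, and probe pressure artifacts. Passing
tests therefore demonstrate the tracker's geometric and statistical
behaviour under controlled speckle-like texture, not clinical
performance.

Two prepackaged analogs mirror the validation experiments:

* `phantom_analog_spec()` — a constant-velocity sweep: 5 mm total over
  206 frames (0.5 mm/s for 10 s), 0.075 mm/px, i.e. ~0.325 px/frame, with
  `rho = 0.05` and noise 0.02. At this speed per-frame integer matching
  loses the motion entirely while chained optical flow drifts by a few
  percent; the combined tracker stays within a few percent of the true
  total (see `scripts/acceptance.R` output), reproducing the
  characteristic ordering combined < flow-only < per-frame matching.
* `tendon_analog_spec()` — sinusoidal or triangular oscillation
  (flexion/extension analog) with `rho = 0.02`, a milder decorrelation
  chosen as representative of in-plane tendon imaging; direction
  reversals exercise the voting tie-break and show why flow-trend
  interpolation places the turning point correctly while linear
  interpolation (the adaptive comparator) can miss it by several frames.

## Comparators and metrics

`track_comparator()` provides the three baselines used throughout:
chained optical flow (`of_only`), per-frame MKBM with template update
(`mkbm_only`; always integer-valued — sub-pixel refinement is an
extension of the combined tracker, not of the baseline — with the
config's fusion rule, `"ncc"` giving the original weighted-average
variant), and `adaptive_mkbm` (same anchors as the combined tracker,
linear interpolation between them). With `lambda_px -> 0` the combined
tracker and `mkbm_only` coincide frame-for-frame, which is asserted in
the tests.

Accuracy is scored on the horizontal component only (tendon motion is
predominantly lateral): `average_absolute_error()` is the mean absolute
difference of frame-to-frame displacements (a cumulative mode exists,
since published displacement curves are cumulative), and
`relative_error()` compares total end-to-end displacements in percent,
undefined (flagged) for zero true displacement. `compare_methods()` runs
all four trackers and tabulates both metrics in pixels and millimetres.

## Problem sizes and determinism

The test suite and the acceptance script regenerate all inputs from code:
five 206-frame phantom replicates for the ranking study, a 312-pair
simulated calibration set, the full ±(20, 10) integer-shift grid (861
matches), and shorter sequences for the remaining contracts — sizes
chosen so the whole suite completes in a few minutes on one core while
keeping every assertion statistically comfortable. Tracking itself is
deterministic (no RNG); all simulator randomness flows through explicit
seeds, and rendering restores the caller's RNG state.

## Known limitations

* Purely translational model: no rotation, shear, or within-region
  deformation; the region is rigid and axis-aligned.
* Horizontal-dominant design: `Da`, the `Va -> N` rule and flow-trend
  interpolation act on x; y is tracked but only linearly interpolated
  within periods.
* Integer template placement (deliberate, to avoid resampling blur)
  leaves a ±0.5 px quantization at anchors unless refinement is enabled.
* Video containers are not decoded directly; sequences are read from
  multi-page TIFF or PNG frame directories (convert videos externally,
  e.g. `ffmpeg -i in.avi frames/%04d.png`).
* The cadaver benchmark (mean E_a ≤ 0.05 mm against an implanted marker)
  requires the original deposited videos, which cannot be redistributed
  here; the corresponding test documents the protocol and fails until
  those data are supplied locally.
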