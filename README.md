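# tendontrack

Speckle tracking of tendon motion in 2-D grayscale image sequences
(musculoskeletal ultrasound B-mode video), for researchers quantifying
tendon excursion during joint motion — e.g. finger flexor tendons at the
A1 pulley or the common extensor tendon at the elbow.

## The method

Tendon sliding is predominantly lateral, sub-millimetre per frame, and
imaged as speckle texture that is noisy at small scales and gradually
decorrelates with out-of-plane motion. Two classical trackers each fail
in one regime:

* **Lucas–Kanade optical flow** — the windowed least-squares solution of
  the brightness-constancy constraint `Ix·Vx + Iy·Vy = −It` — is accurate
  for small motion but underestimates large displacements, and chained
  per-frame estimates drift.
* **Block matching** — exhaustive SAD search,
  `SAD = (1/MN) Σ|T − R|` — is drift-free across long intervals but its
  integer displacements round slow motion to zero, and per-frame template
  updates accumulate that loss.

The package's tracker combines them. Optical flow is reduced to one
region displacement per frame pair (direction voting over a 43 × 13 grid
of flow points; `Va`, the mean speed of the top 5 %, selects through a
calibrated table the percentage `N` of points to average). Signed
horizontal displacements accumulate into `Da`; when `|Da| ≥ λ`
(default 10 px) the elapsed *flow period* is closed and its endpoint
frames are matched by **multi-kernel block matching**: the reference
block is split into four sub-blocks overlapping by 10 px, each matched by
exhaustive SAD search around the flow-predicted position, and the
sub-block with the maximal |horizontal displacement| wins
(`D_t = Max(D_t,1; …; D_t,4)` — rejecting passively dragged neighbouring
tissue). Frames inside the period are interpolated along the flow trend,

    d(t+i) = d_MKBM(t) + (d_OF(t+i) − d_OF(t)) ·
             (d_MKBM(t+n) − d_MKBM(t)) / (d_OF(t+n) − d_OF(t)),

the template moves to the matched position, and the cycle repeats.
Comparators (`of_only`, `mkbm_only`, `adaptive_mkbm`), the error metrics
`E_a` (mean absolute instantaneous-displacement error) and `E_r`
(relative total-displacement error, %), and a speckle simulator with
ground-truth motion are included. See the methods vignette
(`vignettes/oftb-mkbm-methods.Rmd`) for the full model and design
rationale.

## Worked example

Track a simulated speckle sequence translating at 1 px/frame for 40
frames (0.075 mm/px):

```r
library(tendontrack)
sim <- render_sequence(phantom_spec(
  frame_size = c(300L, 150L),
  motion = motion_profile("constant_velocity", n_frames = 40, vx = 1),
  noise_sd = 0.02, rho = 0.02, seed = 7))
roi  <- region(60, 50, 101, 41)
traj <- track(sim$sequence, roi)
traj
#> track_trajectory (oftb_mkbm): 40 frames, 6 anchors
#>   total displacement: dx = 40.000 px, dy = 0.000 px
#>   total dx = 3.0000 mm at 0.075 mm/px
#>   frame     dx_px dy_px    ddx_px ddy_px is_anchor
#> 1     0 0.0000000     0 0.0000000      0      TRUE
#> 2     1 0.9665456     0 0.9665456      0     FALSE
#> 3     2 2.0529204     0 1.0863748      0     FALSE
#> ...
```

The true total is 39 px; the tracker reports 40 px (anchors every ~10
frames, where `|Da|` crossed λ = 10 and block matching re-anchored the
template; the 1 px excess is the final anchor's integer quantization).
Scoring all four methods against the ground truth:

```r
compare_methods(sim$sequence, roi, tracker_config(), sim$motion)
#> Method comparison (x displacement vs ground truth):
#>         method e_a_px e_a_mm e_r_percent total_dx_px rank
#>      oftb_mkbm 0.1459 0.0109       2.564      40.000    1
#>        of_only 0.2101 0.0158      21.012      47.195    4
#>      mkbm_only 0.0256 0.0019       2.564      40.000    1
#>  adaptive_mkbm 0.0256 0.0019       2.564      40.000    1
```

At 1 px/frame the flow-only tracker drifts (+21 %) while the
block-matching-anchored methods agree; the regimes separate at sub-pixel
speeds (see the phantom analog below), where per-frame matching loses
the motion instead. `plot(traj)` draws the cumulative displacement with
anchors marked; `save_trajectory(traj, "traj.csv")` writes the per-frame
CSV.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/tendontrack.R track --input seq.tif --roi 60,50,101,41 \
        --pixel-spacing 0.075 --out traj.csv
Rscript inst/cli/tendontrack.R simulate --spec spec.yaml --out-dir sim/
Rscript inst/cli/tendontrack.R evaluate --pred traj.csv --gt gt.csv
Rscript inst/cli/tendontrack.R calibrate-van --pairs pairs.csv \
        --input seq.tif --roi 60,50,101,41 --out table.csv
```

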