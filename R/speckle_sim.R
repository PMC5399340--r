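# Synthetic ultrasound-like speckle sequences with known ground-truth
# motion.  Speckle is modelled as a field of continuous-coordinate point
# scatterers splatted bilinearly onto the pixel grid and blurred with an
# anisotropic Gaussian point-spread function (narrow axially, wide
# laterally).  Out-of-plane motion is approximated by resampling a
# fraction rho of the scatterers every frame, which decorrelates the
# texture gradually without moving it.

#' Ground-truth motion profile
#'
#' Cumulative per-frame displacement, starting at `(0, 0)`.
#'
#' * `constant_velocity`: `dx(k) = vx * k`.
#' * `sinusoidal`: `dx(k) = amplitude * sin(2*pi*k / period)`.
#' * `triangle`: rises linearly to `+amplitude` at `k = period/2`, falls
#'   to `-amplitude` at `k = 3*period/2`, and so on (direction reversals
#'   at `period/2 + m*period`).
#' * `piecewise`: user-supplied cumulative `dx` (and optional `dy`).
#'
#' @param kind Profile kind.
#' @param n_frames Number of frames.
#' @param vx Pixels/frame for `constant_velocity`.
#' @param amplitude Peak displacement (pixels).
#' @param period Frames per oscillation.
#' @param dx,dy Cumulative displacements for `piecewise`.
#' @return A data frame of class `motion_profile` with columns `frame`
#'   (0-based), `dx`, `dy`.
#' @export
motion_profile <- function(kind = c("constant_velocity", "sinusoidal",
                                    "triangle", "piecewise"),
                           n_frames, vx = 0.5, amplitude = 30, period = 60,
                           dx = NULL, dy = NULL) {
  kind <- match.arg(kind)
  if (n_frames < 2L) stopf("a motion profile needs at least 2 frames")
  k <- seq.int(0L, n_frames - 1L)
  xx <- switch(kind,
    constant_velocity = vx * k,
    sinusoidal = amplitude * sin(2 * pi * k / period),
    triangle = {
      u <- (k / (2 * period)) %% 1
      amplitude * ifelse(u < 0.25, 4 * u,
                         ifelse(u < 0.75, 2 - 4 * u, 4 * u - 4))
    },
    piecewise = {
      if (is.null(dx) || length(dx) != n_frames)
        stopf("piecewise profile needs dx of length n_frames")
      dx
    })
  yy <- if (kind == "piecewise" && !is.null(dy)) dy else rep(0, n_frames)
  if (abs(xx[1]) > 1e-12 || abs(yy[1]) > 1e-12)
    stopf("motion profile must start at (0, 0)")
  structure(data.frame(frame = k, dx = xx, dy = yy),
            class = c("motion_profile", "data.frame"), kind = kind)
}

#' Specify a synthetic speckle phantom
#'
#' @param frame_size `c(width, height)` in pixels.
#' @param motion A [motion_profile()]; its length sets the frame count.
#' @param density Scatterers per square pixel.
#' @param blur `c(lateral, axial)` Gaussian point-spread sigmas (pixels);
#'   lateral (x) resolution is coarser than axial (y), as in B-mode
#'   imaging.
#' @param noise_sd Additive Gaussian noise sigma on `[0, 1]` intensities.
#' @param rho Fraction of scatterers resampled each frame (out-of-plane
#'   decorrelation analog), in `[0, 1)`.
#' @param pixel_spacing mm/pixel.
#' @param frame_rate Frames/second.
#' @param seed RNG seed; identical specs render bit-identical sequences.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(frame_size = c(400L, 200L),
                         motion = motion_profile("constant_velocity",
                                                 n_frames = 60L, vx = 0.5),
                         density = 0.02, blur = c(2, 1), noise_sd = 0.02,
                         rho = 0.02, pixel_spacing = 0.075, frame_rate = 30,
                         seed = 1L) {
  stopifnot(inherits(motion, "motion_profile"))
  if (rho < 0 || rho >= 1) stopf("rho must lie in [0, 1)")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (nrow(motion) < 2L) stopf("need at least 2 frames")
  structure(list(frame_size = as.integer(frame_size), motion = motion,
                 density = density, blur = blur, noise_sd = noise_sd,
                 rho = rho, pixel_spacing = pixel_spacing,
                 frame_rate = frame_rate, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "phantom_spec: %d frames of %d x %d px (%s motion, rho = %g, sigma = %g, seed = %d)\n",
    nrow(x$motion), x$frame_size[1], x$frame_size[2],
    attr(x$motion, "kind"), x$rho, x$noise_sd, x$seed))
  invisible(x)
}

#' Render a synthetic speckle sequence
#'
#' Each frame is the scatterer field shifted by the cumulative ground
#' truth displacement (sub-pixel, through continuous coordinates),
#' splatted, blurred anisotropically, scaled by a fixed global factor and
#' degraded by additive noise; a fraction `rho` of scatterers is
#' resampled every frame.  Deterministic for a fixed seed.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `sequence` (an [image_sequence()]), `motion` (the
#'   ground-truth [motion_profile()]) and `spec`.
#' @export
render_sequence <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  w <- spec$frame_size[1]; h <- spec$frame_size[2]
  mot <- spec$motion
  n_frames <- nrow(mot)
  if (!all(is.finite(mot$dx)) || !all(is.finite(mot$dy)) ||
      max(abs(mot$dx)) > 50 * w || max(abs(mot$dy)) > 50 * h)
    stopf("motion profile pushes the texture fully out of frame")
  pad <- 3 * max(spec$blur) + 3
  x_lo <- -max(mot$dx) - pad; x_hi <- w - min(mot$dx) + pad
  y_lo <- -max(mot$dy) - pad; y_hi <- h - min(mot$dy) + pad
  frames <- with_seed(spec$seed, {
    n_sc <- max(10L, round(spec$density * (x_hi - x_lo) * (y_hi - y_lo)))
    sx <- runif(n_sc, x_lo, x_hi)
    sy <- runif(n_sc, y_lo, y_hi)
    amp <- rexp(n_sc) + 0.05
    scale <- NULL
    out <- vector("list", n_frames)
    for (k in seq_len(n_frames)) {
      if (k > 1L && spec$rho > 0) {
        res <- runif(n_sc) < spec$rho
        nr <- sum(res)
        if (nr > 0L) {
          sx[res] <- runif(nr, x_lo, x_hi)
          sy[res] <- runif(nr, y_lo, y_hi)
          amp[res] <- rexp(nr) + 0.05
        }
      }
      img <- splat_bilinear(sx + mot$dx[k], sy + mot$dy[k], amp, w, h)
      img <- gaussian_blur(img, spec$blur[1], spec$blur[2])
      # fixed global scale mapping bright speckle to ~0.85 so frames fill
      # the dynamic range like B-mode video; same factor for every frame
      if (is.null(scale))
        scale <- 0.85 / (stats::quantile(img, 0.995, names = FALSE) + 1e-12)
      img <- img * scale
      if (spec$noise_sd > 0)
        img <- img + matrix(rnorm(h * w, sd = spec$noise_sd), h, w)
      out[[k]] <- pmin(pmax(img, 0), 1)
    }
    out
  })
  list(sequence = image_sequence(frames, pixel_spacing = spec$pixel_spacing,
                                 frame_rate = spec$frame_rate),
       motion = mot, spec = spec)
}

# Bilinear splat of weighted points onto an h x w grid.  Pixel (row, col)
# corresponds to 0-based (y, x) = (row-1, col-1).
splat_bilinear <- function(px, py, wgt, w, h) {
  ix <- floor(px); iy <- floor(py)
  fx <- px - ix; fy <- py - iy
  acc_idx <- integer(0); acc_w <- numeric(0)
  for (corner in 1:4) {
    cx <- ix + (corner == 2L | corner == 4L)
    cy <- iy + (corner >= 3L)
    ww <- wgt *
      (ifelse(corner %in% c(2L, 4L), fx, 1 - fx)) *
      (ifelse(corner >= 3L, fy, 1 - fy))
    keep <- cx >= 0 & cx < w & cy >= 0 & cy < h & ww > 0
    acc_idx <- c(acc_idx, as.integer(cy[keep] + 1 + cx[keep] * h))
    acc_w <- c(acc_w, ww[keep])
  }
  img <- matrix(0, h, w)
  if (length(acc_idx)) {
    s <- rowsum(acc_w, acc_idx)
    img[as.integer(rownames(s))] <- s[, 1]
  }
  img
}

#' Phantom-analog specification: constant-velocity sweep
#'
#' Emulates a controlled phantom acquisition: a probe translating at
#' 0.5 mm/s for 10 s, i.e. a total displacement of 5 mm over 206 frames.
#' At the default 0.075 mm/px elbow-imaging scale this is 66.67 px total,
#' about 0.325 px/frame — firmly sub-pixel, the regime where per-frame
#' block matching drifts and optical flow slowly underestimates.
#'
#' @param pixel_spacing mm/pixel.
#' @param total_mm Total displacement (mm).
#' @param n_frames Number of frames.
#' @param noise_sd,rho,seed Passed to [phantom_spec()].
#' @return A [phantom_spec()].
#' @export
phantom_analog_spec <- function(pixel_spacing = 0.075, total_mm = 5,
                                n_frames = 206L, noise_sd = 0.02,
                                rho = 0.05, seed = 1L) {
  total_px <- total_mm / pixel_spacing
  mot <- motion_profile("constant_velocity", n_frames = n_frames,
                        vx = total_px / (n_frames - 1L))
  phantom_spec(frame_size = c(400L, 200L), motion = mot,
               noise_sd = noise_sd, rho = rho,
               pixel_spacing = pixel_spacing,
               frame_rate = n_frames / 10, seed = seed)
}

#' Calibrate the Va -> N table on simulated speckle pairs
#'
#' Runs the calibration procedure of [calibrate_va_n()] on synthetic
#' adjacent frame pairs rendered at a range of known constant velocities
#' under the given noise and decorrelation conditions.  This mirrors how
#' the table is calibrated on real data (frame pairs with manually
#' tracked displacement), with the simulator supplying the ground truth.
#'
#' @param config A [tracker_config()] (window/grid/top-fraction settings
#'   used during calibration).
#' @param velocities Ground-truth speeds (px/frame) spanning the Va range
#'   of interest.
#' @param pairs_per_velocity Adjacent frame pairs rendered per speed.
#' @param noise_sd,rho Simulator conditions the table is calibrated for.
#' @param seed Base RNG seed.
#' @return A [va_n_table()].
#' @export
calibrate_va_n_sim <- function(config = tracker_config(),
                               velocities = seq(0.1, 2.6, length.out = 13),
                               pairs_per_velocity = 24L,
                               noise_sd = 0.02, rho = 0.05, seed = 100L) {
  roi <- region(40L, 80L, config$region_size[1], config$region_size[2])
  recs <- list()
  for (i in seq_along(velocities)) {
    v <- velocities[i]
    sp <- phantom_spec(frame_size = c(400L, 200L),
                       motion = motion_profile("constant_velocity",
                                               n_frames = pairs_per_velocity + 1L,
                                               vx = v),
                       noise_sd = noise_sd, rho = rho, seed = seed + i)
    r <- render_sequence(sp)
    for (j in seq_len(pairs_per_velocity)) {
      reg <- region_shift(roi, round(r$motion$dx[j]), 0)
      recs[[length(recs) + 1L]] <-
        list(flow_field = compute_flow_field(r$sequence$frames[[j]],
                                             r$sequence$frames[[j + 1L]],
                                             reg, config),
             gt_dx = v)
    }
  }
  calibrate_va_n(recs, config)
}

#' Study configuration for slow, decorrelating sequences
#'
#' Returns the tracker configuration the package uses for constant-slow
#' (sub-pixel per frame) motion with appreciable frame-to-frame
#' decorrelation, such as the phantom-sweep analog: a reduced
#' accumulation threshold (`lambda_px = 3`) that keeps flow periods
#' within the speckle decorrelation time, a search range sized to the
#' flow-prediction uncertainty rather than the full period displacement,
#' and sub-pixel refinement of the selected block match.
#'
#' @param va_n_table A calibrated [va_n_table()] (see
#'   [calibrate_va_n_sim()]); defaults to the package placeholder table.
#' @param ... Further overrides passed to [tracker_config()].
#' @return A [tracker_config()].
#' @export
slow_motion_config <- function(va_n_table = tendontrack::va_n_table(), ...) {
  tracker_config(lambda_px = 3, search_range = c(6L, 4L),
                 refine_subpixel = TRUE, va_n_table = va_n_table, ...)
}

#' Tendon-analog specification: oscillatory motion with reversals
#'
#' Emulates in vivo flexion/extension: the tendon translates back and
#' forth laterally, exercising the direction voting and the handling of
#' motion reversals inside a flow period.
#'
#' @param kind `"sinusoidal"` or `"triangle"`.
#' @param amplitude Peak displacement (pixels).
#' @param period Frames per oscillation (see [motion_profile()]).
#' @param n_frames Number of frames.
#' @param noise_sd,rho,seed Passed to [phantom_spec()].
#' @param pixel_spacing mm/pixel.
#' @return A [phantom_spec()].
#' @export
tendon_analog_spec <- function(kind = c("sinusoidal", "triangle"),
                               amplitude = 30, period = 60, n_frames = 120L,
                               noise_sd = 0.02, rho = 0.02,
                               pixel_spacing = 0.0265, seed = 1L) {
  kind <- match.arg(kind)
  mot <- motion_profile(kind, n_frames = n_frames, amplitude = amplitude,
                        period = period)
  phantom_spec(frame_size = c(400L, 200L), motion = mot,
               noise_sd = noise_sd, rho = rho,
               pixel_spacing = pixel_spacing, frame_rate = 30, seed = seed)
}
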