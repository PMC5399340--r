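# Windowed Lucas-Kanade optical flow with direction voting and the
# Va -> N top-fraction averaging rule.
#
# The brightness-constancy constraint Ix*Vx + Iy*Vy = -It is solved by
# least squares over a square window: stacking the constraint at every
# window pixel gives the 2x2 normal system
#   [ S(Ix^2)  S(IxIy) ] [Vx]   [ S(IxIt) ]
#   [ S(IxIy)  S(Iy^2) ] [Vy] = -[ S(IyIt) ]
# A point is invalid when this system is near-singular (textureless or
# one-dimensional structure).

# Smoothed spatial/temporal gradients for a frame pair.  Spatial gradients
# are central differences of the smoothed first frame; the temporal
# gradient is the forward difference.  (Gradients anchored at frame t keep
# the estimator in the mild-underestimation regime for larger motions,
# which the adaptive frame-interval logic relies on; averaging both frames
# instead flips the bias to overestimation.)  Outermost rows/cols get zero
# spatial gradient; callers keep windows away from them.
flow_gradients <- function(f0, f1, blur_sigma) {
  s0 <- gaussian_blur(f0, blur_sigma)
  s1 <- gaussian_blur(f1, blur_sigma)
  sm <- s0
  h <- nrow(sm); w <- ncol(sm)
  ix <- matrix(0, h, w); iy <- matrix(0, h, w)
  ix[, 2:(w - 1)] <- (sm[, 3:w] - sm[, 1:(w - 2)]) / 2
  iy[2:(h - 1), ] <- (sm[3:h, ] - sm[1:(h - 2), ]) / 2
  list(ix = ix, iy = iy, it = s1 - s0)
}

# Margin (px) the gradient stencil needs beyond the LK window.
grad_margin <- function(blur_sigma) max(1L, ceiling(3 * blur_sigma)) + 1L

#' Lucas-Kanade flow at a single point
#'
#' Solves the windowed least-squares optical-flow system for one point.
#' The window must lie fully inside both frames.
#'
#' @param frame_t,frame_t1 Two frames (numeric matrices of equal size).
#' @param center `c(x, y)` window centre, 0-based pixel coordinates.
#' @param window Odd window side length (pixels).
#' @param blur_sigma Gaussian pre-smoothing (pixels).
#' @param cond_tol Near-singularity threshold on the eigenvalue ratio of
#'   the normal matrix.
#' @return A list of class `flow_point` with elements `x`, `y`, `vx`, `vy`
#'   (pixels/frame; `NA` when invalid) and `valid`.
#' @export
lucas_kanade_point <- function(frame_t, frame_t1, center, window = 17L,
                               blur_sigma = 1, cond_tol = 1e-6) {
  stopifnot(all(dim(frame_t) == dim(frame_t1)))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stopf("window must be odd and >= 3")
  r <- window %/% 2L
  cx <- as.integer(center[1]); cy <- as.integer(center[2])
  h <- nrow(frame_t); w <- ncol(frame_t)
  if (cx - r < 0L || cy - r < 0L || cx + r >= w || cy + r >= h)
    stopf("flow window at (%d, %d) exceeds frame bounds", cx, cy)
  m <- grad_margin(blur_sigma)
  # crop with replicate padding so the blur/gradient stencil is defined
  y0 <- cy + 1L - r - m; y1 <- cy + 1L + r + m
  x0 <- cx + 1L - r - m; x1 <- cx + 1L + r + m
  g <- flow_gradients(crop_pad(frame_t, y0, y1, x0, x1),
                      crop_pad(frame_t1, y0, y1, x0, x1), blur_sigma)
  sel <- (m + 1L):(m + window)
  sol <- solve_lk(sum(g$ix[sel, sel]^2), sum(g$ix[sel, sel] * g$iy[sel, sel]),
                  sum(g$iy[sel, sel]^2), sum(g$ix[sel, sel] * g$it[sel, sel]),
                  sum(g$iy[sel, sel] * g$it[sel, sel]), cond_tol)
  structure(list(x = cx, y = cy, vx = sol$vx, vy = sol$vy, valid = sol$valid),
            class = "flow_point")
}

# Vectorized 2x2 least-squares solve with eigenvalue-ratio validity test.
solve_lk <- function(sxx, sxy, syy, sxt, syt, cond_tol) {
  tr <- sxx + syy
  disc <- sqrt(pmax((sxx - syy)^2 + 4 * sxy^2, 0))
  lmax <- (tr + disc) / 2
  lmin <- (tr - disc) / 2
  valid <- lmax > 0 & lmin >= cond_tol * lmax
  det <- sxx * syy - sxy^2
  vx <- ifelse(valid, (-sxt * syy + syt * sxy) / det, NA_real_)
  vy <- ifelse(valid, (-syt * sxx + sxt * sxy) / det, NA_real_)
  list(vx = vx, vy = vy, valid = valid)
}

# Grid node offsets (0-based, relative to the region corner) for one axis:
# inset by the window half-width, then every `step` pixels.
grid_offsets <- function(extent, window, step) {
  r <- window %/% 2L
  if (extent - 2L * r < 1L) return(integer(0))
  seq.int(r, extent - 1L - r, by = step)
}

#' Compute a flow field over a region
#'
#' Places flow points on a regular grid inside `region` (inset by half the
#' LK window so every window fits) and solves the Lucas-Kanade system at
#' each node.  With the default 101 x 41 region, 17 x 17 window and 2-px
#' grid step this yields 43 x 13 = 559 flow points.
#'
#' @param frame_t,frame_t1 Two frames (numeric matrices of equal size).
#' @param region A [region()] inside the frame.
#' @param config A [tracker_config()].
#' @return An object of class `flow_field`: a list with matrices `vx`,
#'   `vy`, `valid` (rows x cols of the grid), vectors `gx`, `gy` of
#'   0-based node coordinates, and the region.
#' @export
compute_flow_field <- function(frame_t, frame_t1, region, config = tracker_config()) {
  stopifnot(inherits(region, "region"), all(dim(frame_t) == dim(frame_t1)))
  win <- config$of_window
  gx <- region$x + grid_offsets(region$width, win, config$flow_grid_step)
  gy <- region$y + grid_offsets(region$height, win, config$flow_grid_step)
  h <- nrow(frame_t); w <- ncol(frame_t)
  r <- win %/% 2L
  # windows must lie inside the frame; drop nodes too close to the border
  gx <- gx[gx - r >= 0L & gx + r < w]
  gy <- gy[gy - r >= 0L & gy + r < h]
  if (length(gx) == 0L || length(gy) == 0L)
    stopf("region too small for a single %d x %d flow window", win, win)
  m <- grad_margin(config$blur_sigma)
  x0 <- min(gx) + 1L - r - m; x1 <- max(gx) + 1L + r + m
  y0 <- min(gy) + 1L - r - m; y1 <- max(gy) + 1L + r + m
  g <- flow_gradients(crop_pad(frame_t, y0, y1, x0, x1),
                      crop_pad(frame_t1, y0, y1, x0, x1), config$blur_sigma)
  # grid node positions within the crop (1-based)
  cyl <- (gy + 1L) - y0 + 1L
  cxl <- (gx + 1L) - x0 + 1L
  sxx <- window_sums(g$ix^2,       cyl, cxl, r)
  sxy <- window_sums(g$ix * g$iy,  cyl, cxl, r)
  syy <- window_sums(g$iy^2,       cyl, cxl, r)
  sxt <- window_sums(g$ix * g$it,  cyl, cxl, r)
  syt <- window_sums(g$iy * g$it,  cyl, cxl, r)
  sol <- solve_lk(sxx, sxy, syy, sxt, syt, config$cond_tol)
  structure(list(vx = matrix(sol$vx, length(gy), length(gx)),
                 vy = matrix(sol$vy, length(gy), length(gx)),
                 valid = matrix(sol$valid, length(gy), length(gx)),
                 gx = gx, gy = gy, region = region),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("flow_field: %d x %d points (%d valid) in %d x %d px region\n",
              length(x$gx), length(x$gy), sum(x$valid),
              x$region$width, x$region$height))
  invisible(x)
}

#' Classify the horizontal motion direction of a flow value
#'
#' @param vx Horizontal velocity (pixels/frame), finite.
#' @return `"left"` if `vx < 0`, `"right"` if `vx > 0`, `"ignored"` if
#'   exactly zero.  Vectorized.
#' @export
classify_direction <- function(vx) {
  stopifnot(all(is.finite(vx)))
  ifelse(vx < 0, "left", ifelse(vx > 0, "right", "ignored"))
}

#' Reduce a flow field to one region displacement
#'
#' Implements the outlier-excluding reduction: invalid points are dropped;
#' the remainder vote by horizontal direction and only the majority class
#' is retained; `Va` is the mean |vx| of the top `top_fraction` retained
#' points; the calibration table converts `Va` to a percentage `N`; the
#' region displacement is the mean (signed) velocity of the top `N`\%
#' retained points ranked by |vx|.
#'
#' @param flow_field A [compute_flow_field()] result.
#' @param config A [tracker_config()] (supplies `top_fraction` and the
#'   `va_n_table`).
#' @param prev_direction Direction of the previous frame pair (`"left"`,
#'   `"right"` or `NULL`), used to break an exact left/right voting tie.
#' @param n_override Optional percentage forcing `N` (bypasses the table).
#' @return A list of class `region_displacement`: `dx`, `dy`
#'   (pixels/frame), `direction` (`"left"`, `"right"` or `"none"`),
#'   `n_points_used`, `va`, `n_percent`, `degenerate`.
#' @export
region_displacement <- function(flow_field, config = tracker_config(),
                                prev_direction = NULL, n_override = NULL) {
  vx <- as.vector(flow_field$vx)
  vy <- as.vector(flow_field$vy)
  ok <- as.vector(flow_field$valid) & is.finite(vx) & is.finite(vy)
  vx <- vx[ok]; vy <- vy[ok]
  none <- structure(list(dx = 0, dy = 0, direction = "none",
                         n_points_used = 0L, va = NA_real_,
                         n_percent = NA_real_, degenerate = TRUE),
                    class = "region_displacement")
  if (length(vx) == 0L) return(none)
  dir <- classify_direction(vx)
  n_left <- sum(dir == "left"); n_right <- sum(dir == "right")
  if (n_left == 0L && n_right == 0L) return(none)
  keep_dir <- if (n_left > n_right) "left"
  else if (n_right > n_left) "right"
  else if (!is.null(prev_direction) && prev_direction %in% c("left", "right"))
    prev_direction
  else return(none)
  sel <- dir == keep_dir
  vx <- vx[sel]; vy <- vy[sel]
  m <- length(vx)
  ord <- order(-abs(vx))
  k_va <- max(1L, ceiling(config$top_fraction * m))
  va <- mean(abs(vx)[ord[seq_len(k_va)]])
  n_pct <- if (!is.null(n_override)) n_override
  else lookup_n(config$va_n_table, va)
  k_n <- max(1L, ceiling(n_pct / 100 * m))
  top <- ord[seq_len(k_n)]
  structure(list(dx = mean(vx[top]), dy = mean(vy[top]),
                 direction = keep_dir, n_points_used = k_n,
                 va = va, n_percent = n_pct, degenerate = FALSE),
            class = "region_displacement")
}

#' @export
print.region_displacement <- function(x, ...) {
  cat(sprintf(
    "region_displacement: dx = %.4f, dy = %.4f px/frame (%s, Va = %.3f, N = %.1f%%, %d pts)\n",
    x$dx, x$dy, x$direction, x$va, x$n_percent, x$n_points_used))
  invisible(x)
}

#' Calibrate the Va -> N table from frame pairs with known displacement
#'
#' For each record the retained (majority-direction) flow points are
#' ranked by |vx|; `Va` is computed as in [region_displacement()]; the
#' smallest percentage `N` whose top-`N`\% mean matches the ground-truth
#' horizontal displacement within `tol` is recorded (if none matches, the
#' best-fitting `N`).  The `(Va, N)` pairs are binned over `Va`, averaged
#' per bin, and made monotone non-increasing by isotonic regression.
#'
#' @param records List of records, each a list with elements `flow_field`
#'   (a [compute_flow_field()] result) and `gt_dx` (ground-truth horizontal
#'   region displacement, pixels/frame).
#' @param config A [tracker_config()].
#' @param tol Matching tolerance in pixels.
#' @param n_bins Number of equal-width Va bins for the knots.
#' @return A [va_n_table()].
#' @export
calibrate_va_n <- function(records, config = tracker_config(), tol = 0.05,
                           n_bins = 6L) {
  if (length(records) < 10L)
    stopf("calibration needs at least 10 frame pairs (got %d)", length(records))
  vas <- numeric(0); ns <- numeric(0)
  for (rec in records) {
    ff <- rec$flow_field
    vx <- as.vector(ff$vx)
    ok <- as.vector(ff$valid) & is.finite(vx)
    vx <- vx[ok]
    if (length(vx) == 0L) next
    dir <- classify_direction(vx)
    n_left <- sum(dir == "left"); n_right <- sum(dir == "right")
    if (n_left == 0L && n_right == 0L) next
    keep <- if (n_left >= n_right) "left" else "right"
    vx <- vx[dir == keep]
    m <- length(vx)
    ord <- order(-abs(vx))
    k_va <- max(1L, ceiling(config$top_fraction * m))
    va <- mean(abs(vx)[ord[seq_len(k_va)]])
    # candidate means for every percentage 1..100
    kk <- pmax(1L, ceiling((1:100) / 100 * m))
    cmeans <- cumsum(vx[ord]) / seq_len(m)
    err <- abs(cmeans[kk] - rec$gt_dx)
    hit <- which(err <= tol)
    n_best <- if (length(hit)) hit[1] else which.min(err)
    vas <- c(vas, va); ns <- c(ns, n_best)
  }
  if (length(vas) < 10L)
    stopf("calibration needs at least 10 usable frame pairs (got %d)", length(vas))
  # bin Va, average N per bin
  rng <- range(vas)
  if (diff(rng) < 1e-12) return(va_n_table(rng[1], mean(ns)))
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- cut(vas, breaks, include.lowest = TRUE, labels = FALSE)
  knot_va <- tapply(vas, bin, mean)
  knot_n <- tapply(ns, bin, mean)
  o <- order(knot_va)
  knot_va <- as.numeric(knot_va[o]); knot_n <- as.numeric(knot_n[o])
  if (length(knot_va) > 1L) {
    # monotone non-increasing N over Va
    iso <- isoreg(knot_va, -knot_n)
    knot_n <- -iso$yf
    dup <- c(FALSE, diff(knot_va) <= 1e-12)
    knot_va <- knot_va[!dup]; knot_n <- knot_n[!dup]
  }
  va_n_table(knot_va, pmin(pmax(knot_n, 1), 100))
}
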