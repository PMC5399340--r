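# Trajectory error metrics and the four-method comparison harness.
# Validation uses the horizontal (x) component only, matching the
# predominantly lateral direction of tendon motion.

# Extract cumulative x displacement from a trajectory object, a
# motion_profile, or a data frame with dx_px/dx columns.
cum_x <- function(obj) {
  df <- as.data.frame(obj)
  if ("dx_px" %in% names(df)) return(df$dx_px)
  if ("dx" %in% names(df)) return(df$dx)
  stopf("cannot find a horizontal displacement column (dx_px or dx)")
}

#' Average absolute instantaneous-displacement error (E_a)
#'
#' `E_a = sum(|d_GT,t - d_PA,t|) / N` over the `N` frame-to-frame
#' horizontal displacements of the two trajectories (or, with
#' `mode = "cumulative"`, over the cumulative displacements).
#'
#' @param gt,pred Trajectories ([track_trajectory()], [motion_profile()]
#'   or data frames) of equal length.
#' @param mode Compare `"instantaneous"` (frame-to-frame deltas, the
#'   default) or `"cumulative"` displacements.
#' @param pixel_spacing Optional mm/pixel; when given, the result carries
#'   an `mm` attribute with the metric converted to millimetres.
#' @return `E_a` in pixels (non-negative scalar).
#' @export
average_absolute_error <- function(gt, pred,
                                   mode = c("instantaneous", "cumulative"),
                                   pixel_spacing = NULL) {
  mode <- match.arg(mode)
  g <- cum_x(gt); p <- cum_x(pred)
  if (length(g) != length(p))
    stopf("trajectories differ in length (%d vs %d)", length(g), length(p))
  if (length(g) < 2L) stopf("need at least 2 frames")
  if (mode == "instantaneous") { g <- diff(g); p <- diff(p) }
  ea <- mean(abs(g - p))
  if (!is.null(pixel_spacing)) attr(ea, "mm") <- ea * pixel_spacing[1]
  ea
}

#' Relative total-displacement error (E_r)
#'
#' `E_r = |(D_GT - D_PA) / D_GT| * 100`\%, where the total displacement
#' `D` is the cumulative horizontal displacement of the final frame
#' relative to the first.
#'
#' @param gt,pred Trajectories of equal length.
#' @return `E_r` in percent; `NA` with a warning when `D_GT = 0`.
#' @export
relative_error <- function(gt, pred) {
  g <- cum_x(gt); p <- cum_x(pred)
  if (length(g) != length(p))
    stopf("trajectories differ in length (%d vs %d)", length(g), length(p))
  d_gt <- g[length(g)] - g[1]
  d_pa <- p[length(p)] - p[1]
  if (abs(d_gt) < 1e-12) {
    warnf("relative error undefined: ground-truth total displacement is zero")
    return(NA_real_)
  }
  abs((d_gt - d_pa) / d_gt) * 100
}

#' Compare the four tracking methods against ground truth
#'
#' Runs OFTB-MKBM and the three comparators (`of_only`, `mkbm_only`,
#' `adaptive_mkbm`) on a sequence and scores each against the ground
#' truth with [average_absolute_error()] and [relative_error()].
#'
#' @param sequence An [image_sequence()].
#' @param initial_region A [region()] in frame 0.
#' @param config A [tracker_config()].
#' @param gt Ground-truth trajectory aligned to the sequence.
#' @param pixel_spacing mm/pixel for the mm column (defaults to the
#'   sequence's).
#' @return A data frame of class `method_comparison` with one row per
#'   method: `method`, `e_a_px`, `e_a_mm`, `e_r_percent`, `total_dx_px`,
#'   plus a `rank` by `e_r_percent`.  Trajectories are attached as
#'   `attr(, "trajectories")`.
#' @export
compare_methods <- function(sequence, initial_region,
                            config = tracker_config(), gt,
                            pixel_spacing = NULL) {
  ps <- if (!is.null(pixel_spacing)) pixel_spacing[1]
  else sequence$pixel_spacing[1]
  trajs <- list(
    oftb_mkbm = track(sequence, initial_region, config),
    of_only = track_comparator(sequence, initial_region, config, "of_only"),
    mkbm_only = track_comparator(sequence, initial_region, config, "mkbm_only"),
    adaptive_mkbm = track_comparator(sequence, initial_region, config,
                                     "adaptive_mkbm"))
  gt_x <- cum_x(gt)
  rows <- lapply(names(trajs), function(nm) {
    tr <- trajs[[nm]]
    n <- nrow(tr)
    g <- gt_x[seq_len(n)]                 # align to (possibly truncated) track
    ea <- average_absolute_error(data.frame(dx = g), tr)
    er <- relative_error(data.frame(dx = g), tr)
    data.frame(method = nm, e_a_px = ea,
               e_a_mm = if (is.finite(ps)) ea * ps else NA_real_,
               e_r_percent = er, total_dx_px = tr$dx_px[n])
  })
  out <- do.call(rbind, rows)
  out$rank <- rank(out$e_r_percent, ties.method = "min")
  structure(out, class = c("method_comparison", "data.frame"),
            trajectories = trajs)
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("Method comparison (x displacement vs ground truth):\n")
  df <- as.data.frame(x)
  df$e_a_px <- round(df$e_a_px, 4)
  df$e_a_mm <- round(df$e_a_mm, 4)
  df$e_r_percent <- round(df$e_r_percent, 3)
  df$total_dx_px <- round(df$total_dx_px, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
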