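#' Construct a trajectory object
#'
#' A `track_trajectory` is a data frame with one row per frame holding the
#' cumulative displacement of the tracked region relative to frame 0, the
#' frame-to-frame (instantaneous) displacement, and a flag marking anchor
#' frames — frames that ended a flow period, where block matching was
#' applied and the template updated.
#'
#' @param frame 0-based frame indices.
#' @param dx,dy Cumulative displacement in pixels relative to frame 0.
#' @param is_anchor Logical anchor flags.
#' @param method,pixel_spacing,frame_rate,periods,config Optional metadata
#'   stored as attributes.
#' @return A data frame of class `track_trajectory` with columns `frame`,
#'   `dx_px`, `dy_px`, `ddx_px`, `ddy_px`, `is_anchor`.
#' @export
track_trajectory <- function(frame, dx, dy, is_anchor,
                             method = NA_character_,
                             pixel_spacing = NA_real_,
                             frame_rate = NA_real_,
                             periods = NULL, config = NULL) {
  n <- length(frame)
  stopifnot(length(dx) == n, length(dy) == n, length(is_anchor) == n, n >= 1L)
  if (abs(dx[1]) > 1e-12 || abs(dy[1]) > 1e-12)
    stopf("cumulative displacement at frame 0 must be (0, 0)")
  df <- data.frame(frame = as.integer(frame),
                   dx_px = as.numeric(dx), dy_px = as.numeric(dy),
                   ddx_px = c(0, diff(dx)), ddy_px = c(0, diff(dy)),
                   is_anchor = as.logical(is_anchor))
  structure(df, class = c("track_trajectory", "data.frame"),
            method = method, pixel_spacing = pixel_spacing,
            frame_rate = frame_rate, periods = periods, config = config)
}

#' @export
print.track_trajectory <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("track_trajectory (%s): %d frames, %d anchors\n",
              attr(x, "method"), n, sum(x$is_anchor)))
  cat(sprintf("  total displacement: dx = %.3f px, dy = %.3f px\n",
              x$dx_px[n], x$dy_px[n]))
  ps <- attr(x, "pixel_spacing")
  if (length(ps) && is.finite(ps[1]))
    cat(sprintf("  total dx = %.4f mm at %g mm/px\n", x$dx_px[n] * ps[1], ps[1]))
  print.data.frame(head(as.data.frame(x), 6L))
  if (n > 6L) cat(sprintf("  ... %d more frames\n", n - 6L))
  invisible(x)
}

#' @export
summary.track_trajectory <- function(object, ...) {
  n <- nrow(object)
  out <- list(method = attr(object, "method"),
              n_frames = n,
              n_anchors = sum(object$is_anchor),
              total_dx_px = object$dx_px[n],
              total_dy_px = object$dy_px[n],
              max_abs_step_px = max(abs(object$ddx_px)),
              mean_abs_step_px = mean(abs(object$ddx_px[-1])))
  class(out) <- "summary.track_trajectory"
  out
}

#' @export
print.summary.track_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory summary (%s)\n", x$method))
  cat(sprintf("  frames: %d, anchors: %d\n", x$n_frames, x$n_anchors))
  cat(sprintf("  total displacement: (%.3f, %.3f) px\n",
              x$total_dx_px, x$total_dy_px))
  cat(sprintf("  per-frame |dx|: mean %.3f px, max %.3f px\n",
              x$mean_abs_step_px, x$max_abs_step_px))
  invisible(x)
}

#' Plot a trajectory
#'
#' Plots the cumulative horizontal displacement against frame index and
#' marks anchor frames, the frames where block matching re-anchored the
#' track.
#'
#' @param x A [track_trajectory()].
#' @param ... Passed to [plot()].
#' @export
plot.track_trajectory <- function(x, ...) {
  plot(x$frame, x$dx_px, type = "l", xlab = "frame",
       ylab = "cumulative dx (px)",
       main = sprintf("Tracked displacement (%s)", attr(x, "method")), ...)
  points(x$frame[x$is_anchor], x$dx_px[x$is_anchor], pch = 19, cex = 0.7)
  invisible(x)
}
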