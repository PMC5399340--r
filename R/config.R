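#' Default calibration table mapping Va to the averaging percentage N
#'
#' The tracker converts a grid of optical-flow estimates into one region
#' displacement by averaging the top `N`\% of flow points ranked by
#' horizontal speed, where `N` depends on the mean speed `Va` of the top
#' 5\% of points: when the region moves fast, the fastest few points are
#' trustworthy; when it barely moves, a broad average suppresses noise.
#' The anchor point of the default table is `Va = 1.5 px -> N = 20`\%; the
#' remaining knots form a monotone placeholder curve that users should
#' recalibrate for their own imaging setup with [calibrate_va_n()].
#'
#' @param va Numeric vector of Va knots (pixels/frame), strictly increasing.
#' @param n_percent Matching percentages, each in `(0, 100]`.
#' @return An object of class `va_n_table`.
#' @seealso [calibrate_va_n()], [region_displacement()]
#' @export
va_n_table <- function(va = c(0.5, 1.0, 1.5, 2.0, 3.0),
                       n_percent = c(60, 35, 20, 10, 5)) {
  va <- as.numeric(va); n_percent <- as.numeric(n_percent)
  if (length(va) != length(n_percent) || length(va) < 1L)
    stopf("va and n_percent must have equal positive length")
  if (length(va) > 1L && any(diff(va) <= 0))
    stopf("va knots must be strictly increasing")
  if (any(n_percent <= 0) || any(n_percent > 100))
    stopf("n_percent values must lie in (0, 100]")
  structure(list(va = va, n_percent = n_percent), class = "va_n_table")
}

#' Look up the averaging percentage N for a given Va
#'
#' Piecewise-linear interpolation between the table knots, clamped to the
#' first/last knot outside the calibrated range.
#'
#' @param table A [va_n_table()].
#' @param va Va value(s) in pixels/frame.
#' @return Percentage(s) in `(0, 100]`.
#' @export
lookup_n <- function(table, va) {
  stopifnot(inherits(table, "va_n_table"))
  if (length(table$va) == 1L) return(rep(table$n_percent, length(va)))
  approx(table$va, table$n_percent, xout = va, rule = 2)$y
}

#' @export
print.va_n_table <- function(x, ...) {
  cat("Va -> N calibration table:\n")
  print(data.frame(va_px = x$va, n_percent = x$n_percent), row.names = FALSE)
  invisible(x)
}

#' Tracker configuration
#'
#' Bundles every tunable of the OFTB-MKBM tracker.  Defaults reproduce the
#' tendon-imaging settings: accumulated-displacement threshold
#' `lambda_px = 10`, a 17 x 17 Lucas-Kanade window, flow points every 2 px
#' inside a 101 x 41 px region, sub-blocks overlapping by 10 px, and Va
#' computed from the top 5\% of flow points.
#'
#' @param lambda_px Accumulated horizontal displacement (pixels) that ends a
#'   flow period and triggers block matching.  Must be > 0.
#' @param of_window Odd side length of the Lucas-Kanade window (pixels).
#' @param flow_grid_step Spacing of flow points inside the region (pixels).
#' @param region_size `c(width, height)` of the tracking region (pixels).
#' @param subblock_overlap Overlap between adjacent sub-blocks (pixels).
#' @param search_range `c(x, y)` half-range of the exhaustive SAD search
#'   (pixels), applied around the flow-predicted position.
#' @param top_fraction Fraction of retained flow points used to compute Va.
#' @param va_n_table A [va_n_table()] mapping Va to the averaging percentage.
#' @param interpolation_mode `"flow_trend"` (scale intermediate frames by
#'   the optical-flow trend) or `"linear"` (linear in frame index; the
#'   adaptive-MKBM comparator).
#' @param blur_sigma Gaussian pre-smoothing applied before gradient
#'   computation (pixels).
#' @param cond_tol Condition threshold: a flow point is invalid when the
#'   smallest eigenvalue of the 2x2 normal matrix is below
#'   `cond_tol` times the largest.
#' @param fusion Sub-block fusion rule: `"magnitude"` (default; keep the
#'   sub-block with the largest |horizontal displacement|), `"signed"`, or
#'   `"ncc"` (normalized-cross-correlation-weighted average, the original
#'   multi-kernel fusion).
#' @param refine_subpixel When `TRUE`, block matches are refined to
#'   sub-pixel precision (see [match_subblock()]).  Off by default.
#' @return An object of class `tracker_config`.
#' @export
tracker_config <- function(lambda_px = 10,
                           of_window = 17L,
                           flow_grid_step = 2L,
                           region_size = c(101L, 41L),
                           subblock_overlap = 10L,
                           search_range = c(20L, 10L),
                           top_fraction = 0.05,
                           va_n_table = tendontrack::va_n_table(),
                           interpolation_mode = c("flow_trend", "linear"),
                           blur_sigma = 1,
                           cond_tol = 1e-6,
                           fusion = c("magnitude", "signed", "ncc"),
                           refine_subpixel = FALSE) {
  interpolation_mode <- match.arg(interpolation_mode)
  fusion <- match.arg(fusion)
  cfg <- list(lambda_px = as.numeric(lambda_px),
              of_window = as.integer(of_window),
              flow_grid_step = as.integer(flow_grid_step),
              region_size = as.integer(region_size),
              subblock_overlap = as.integer(subblock_overlap),
              search_range = as.integer(search_range),
              top_fraction = as.numeric(top_fraction),
              va_n_table = va_n_table,
              interpolation_mode = interpolation_mode,
              blur_sigma = as.numeric(blur_sigma),
              cond_tol = as.numeric(cond_tol),
              fusion = fusion,
              refine_subpixel = isTRUE(refine_subpixel))
  validate_config(cfg)
  structure(cfg, class = "tracker_config")
}

validate_config <- function(cfg) {
  if (!is.finite(cfg$lambda_px) || cfg$lambda_px <= 0)
    stopf("invalid config value for 'lambda_px': must be > 0")
  if (cfg$of_window < 3L || cfg$of_window %% 2L == 0L)
    stopf("invalid config value for 'of_window': must be odd and >= 3")
  if (cfg$flow_grid_step < 1L)
    stopf("invalid config value for 'flow_grid_step': must be >= 1")
  if (length(cfg$region_size) != 2L || any(cfg$region_size < 3L))
    stopf("invalid config value for 'region_size': need c(width, height) >= 3")
  if (cfg$subblock_overlap < 0L || cfg$subblock_overlap %% 2L != 0L)
    stopf("invalid config value for 'subblock_overlap': must be even and >= 0")
  if (length(cfg$search_range) != 2L || any(cfg$search_range < 1L))
    stopf("invalid config value for 'search_range': need c(x, y) >= 1")
  if (cfg$top_fraction <= 0 || cfg$top_fraction > 1)
    stopf("invalid config value for 'top_fraction': must be in (0, 1]")
  if (!inherits(cfg$va_n_table, "va_n_table"))
    stopf("invalid config value for 'va_n_table': not a va_n_table")
  invisible(TRUE)
}

#' @export
print.tracker_config <- function(x, ...) {
  cat("tracker_config:\n")
  cat(sprintf("  lambda_px       : %g\n", x$lambda_px))
  cat(sprintf("  of_window       : %d x %d\n", x$of_window, x$of_window))
  cat(sprintf("  flow_grid_step  : %d px\n", x$flow_grid_step))
  cat(sprintf("  region_size     : %d x %d px\n",
              x$region_size[1], x$region_size[2]))
  cat(sprintf("  subblock_overlap: %d px\n", x$subblock_overlap))
  cat(sprintf("  search_range    : +/-%d x, +/-%d y px\n",
              x$search_range[1], x$search_range[2]))
  cat(sprintf("  top_fraction    : %g,  interpolation: %s,  fusion: %s\n",
              x$top_fraction, x$interpolation_mode, x$fusion))
  invisible(x)
}

#' Load a tracker configuration from a YAML file
#'
#' Missing keys fall back to the defaults of [tracker_config()].  The
#' `va_n_table` key, if present, must be a mapping with `va` and
#' `n_percent` lists.
#'
#' @param path Path to a YAML (or flat `key: value`) file.
#' @return A [tracker_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(tracker_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  if (!is.null(raw$va_n_table))
    raw$va_n_table <- va_n_table(raw$va_n_table$va, raw$va_n_table$n_percent)
  do.call(tracker_config, raw)
}

#' Write a tracker configuration to a YAML file
#'
#' @param config A [tracker_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "tracker_config"))
  out <- unclass(config)
  out$va_n_table <- list(va = config$va_n_table$va,
                         n_percent = config$va_n_table$n_percent)
  yaml::write_yaml(out, path)
  invisible(path)
}
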