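# OFTB-MKBM orchestration: accumulate optical-flow displacement until it
# exceeds lambda, block-match the flow period's endpoint frames, spread
# the matched displacement over the intermediate frames along the
# optical-flow trend, update the template, repeat.

#' Accumulate optical flow until the displacement threshold is reached
#'
#' Starting at `start_frame`, computes the region displacement of every
#' adjacent frame pair (the region following the rounded cumulative flow)
#' and sums the signed horizontal components into the accumulated
#' displacement `Da`.  The period ends at the first frame where
#' `|Da| >= lambda_px`, or at the end of the sequence.
#'
#' @param sequence An [image_sequence()].
#' @param start_frame 0-based start frame.
#' @param region A [region()] at its position in `start_frame`.
#' @param config A [tracker_config()].
#' @param prev_direction Carry-over direction for the voting tie-break.
#' @param flow_fn Estimator called per frame pair as
#'   `flow_fn(sequence, pair_index, region, config, prev_direction)` and
#'   returning a [region_displacement()].  The default runs the
#'   Lucas-Kanade pipeline; injectable to plug in a custom estimator.
#' @return A list of class `flow_period` with `start`, `end` (0-based
#'   frames), `dof_x`, `dof_y` (cumulative flow displacement over the
#'   period, `dof[1] = 0`), `da` (final accumulated horizontal
#'   displacement), `pairs` (per-pair diagnostics: dx, dy, direction, Va,
#'   N), `direction` (last non-none direction) and `truncated` (TRUE when
#'   the drifting region hit the frame border).
#' @export
accumulate_until_threshold <- function(sequence, start_frame, region, config,
                                       prev_direction = NULL,
                                       flow_fn = NULL) {
  stopifnot(inherits(sequence, "image_sequence"))
  start_frame <- as.integer(start_frame)
  n_frames <- length(sequence$frames)
  if (start_frame >= n_frames - 1L)
    stopf("start_frame %d is the last frame", start_frame)
  if (is.null(flow_fn))
    flow_fn <- function(seq, pair, reg, cfg, prev) {
      region_displacement(
        compute_flow_field(seq$frames[[pair + 1L]], seq$frames[[pair + 2L]],
                           reg, cfg),
        cfg, prev_direction = prev)
    }
  dof_x <- 0; dof_y <- 0
  pairs <- list()
  truncated <- FALSE
  t <- start_frame
  repeat {
    pair <- t + length(dof_x) - 1L          # 0-based index of the pair's first frame
    shifted <- tryCatch(
      region_shift(region, round(dof_x[length(dof_x)]),
                   round(dof_y[length(dof_y)])),
      error = function(e) NULL)
    if (is.null(shifted) ||
        !region_inside(shifted, sequence$height, sequence$width)) {
      truncated <- TRUE
      break
    }
    rd <- flow_fn(sequence, pair, shifted, config, prev_direction)
    if (rd$direction %in% c("left", "right")) prev_direction <- rd$direction
    pairs[[length(pairs) + 1L]] <-
      list(dx = rd$dx, dy = rd$dy, direction = rd$direction,
           va = rd$va, n_percent = rd$n_percent)
    dof_x <- c(dof_x, dof_x[length(dof_x)] + rd$dx)
    dof_y <- c(dof_y, dof_y[length(dof_y)] + rd$dy)
    if (abs(dof_x[length(dof_x)]) >= config$lambda_px) break
    if (pair + 1L >= n_frames - 1L) break   # sequence end
  }
  structure(list(start = start_frame,
                 end = start_frame + length(dof_x) - 1L,
                 dof_x = dof_x, dof_y = dof_y,
                 da = dof_x[length(dof_x)],
                 pairs = pairs, direction = prev_direction,
                 truncated = truncated),
            class = "flow_period")
}

#' Interpolate per-frame displacements inside a flow period
#'
#' Distributes the block-matching displacement of a flow period's
#' endpoints over the intermediate frames proportionally to the
#' optical-flow trend:
#' `d(t+i) = d_MKBM(t) + (d_OF(t+i) - d_OF(t)) *
#'   (d_MKBM(t+n) - d_MKBM(t)) / (d_OF(t+n) - d_OF(t))`.
#' Both endpoints equal the block-matching values exactly.  When the flow
#' trend is degenerate (`d_OF(t+n) = d_OF(t)`), interpolation falls back
#' to linear in the frame index and the result is flagged.
#'
#' @param dof Cumulative optical-flow displacement over the period
#'   (length `n + 1`, first element 0 by convention).
#' @param d_start,d_end Anchor displacements from block matching.
#' @param mode `"flow_trend"` or `"linear"`.
#' @return Numeric vector of length `n + 1` with attribute `fallback`
#'   (TRUE when the linear fallback was used).
#' @export
interpolate_period <- function(dof, d_start, d_end,
                               mode = c("flow_trend", "linear")) {
  mode <- match.arg(mode)
  n <- length(dof) - 1L
  if (n < 1L) stopf("a flow period spans at least 2 frames")
  span <- dof[n + 1L] - dof[1L]
  fallback <- FALSE
  if (mode == "linear" || abs(span) < 1e-12) {
    fallback <- mode != "linear"
    out <- d_start + (seq(0L, n) / n) * (d_end - d_start)
  } else {
    out <- d_start + (dof - dof[1L]) * (d_end - d_start) / span
  }
  out[1L] <- d_start
  out[n + 1L] <- d_end
  structure(out, fallback = fallback)
}

# Shared period-driven tracking loop.  `interp` selects how intermediate
# frames are filled: "flow_trend" (OFTB-MKBM) or "linear" (adaptive MKBM).
track_periods <- function(sequence, initial_region, config, interp) {
  n_frames <- length(sequence$frames)
  cum_x <- rep(NA_real_, n_frames)
  cum_y <- rep(NA_real_, n_frames)
  anchor <- rep(FALSE, n_frames)
  cum_x[1] <- 0; cum_y[1] <- 0; anchor[1] <- TRUE
  periods <- list()
  t <- 0L
  mk_x <- 0; mk_y <- 0                    # cumulative MKBM displacement at anchor
  prev_dir <- NULL
  truncated <- FALSE
  while (t < n_frames - 1L) {
    reg <- region_shift(initial_region, round(mk_x), round(mk_y))
    per <- accumulate_until_threshold(sequence, t, reg, config,
                                      prev_direction = prev_dir)
    prev_dir <- per$direction
    n <- per$end - per$start
    if (n < 1L) { truncated <- TRUE; break }
    template <- block_template(sequence$frames[[t + 1L]], reg, frame_index = t)
    predicted <- c(round(per$dof_x[n + 1L]), round(per$dof_y[n + 1L]))
    bd <- tryCatch(
      mkbm_displacement(template, sequence$frames[[per$end + 1L]],
                        predicted = predicted, config = config),
      error = function(e) NULL)
    if (is.null(bd)) { truncated <- TRUE; break }
    end_x <- mk_x + bd$dx
    end_y <- mk_y + bd$dy
    ix <- interpolate_period(per$dof_x, mk_x, end_x, mode = interp)
    iy <- interpolate_period(per$dof_y, mk_y, end_y, mode = "linear")
    idx <- (t + 1L):(per$end + 1L)        # 1-based frame rows
    cum_x[idx] <- ix
    cum_y[idx] <- iy
    anchor[per$end + 1L] <- TRUE
    periods[[length(periods) + 1L]] <-
      list(start = per$start, n = n, da = per$da,
           d_mkbm = c(bd$dx, bd$dy), contributing = bd$contributing,
           fallback = isTRUE(attr(ix, "fallback")),
           va = vapply(per$pairs, function(p) p$va %||% NA_real_, numeric(1)),
           n_percent = vapply(per$pairs,
                              function(p) p$n_percent %||% NA_real_,
                              numeric(1)))
    mk_x <- end_x; mk_y <- end_y
    t <- per$end
    if (per$truncated) { truncated <- TRUE; break }
  }
  keep <- !is.na(cum_x)
  if (truncated && sum(keep) < n_frames)
    warnf("track truncated at frame %d/%d (region reached the frame border)",
          sum(keep) - 1L, n_frames - 1L)
  track_trajectory(frame = which(keep) - 1L,
                   dx = cum_x[keep], dy = cum_y[keep],
                   is_anchor = anchor[keep],
                   method = if (interp == "flow_trend") "oftb_mkbm"
                   else "adaptive_mkbm",
                   pixel_spacing = sequence$pixel_spacing,
                   frame_rate = sequence$frame_rate,
                   periods = periods, config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Track a region through a sequence with OFTB-MKBM
#'
#' Runs the full tracker: optical flow accumulates frame-to-frame region
#' displacement until `|Da| >= lambda_px`, closing a flow period; the
#' period's endpoint frames are matched by multi-kernel block matching;
#' intermediate frames are interpolated along the flow trend; the region
#' and template move to the matched position and the process repeats to
#' the end of the sequence (a final partial period is still matched).
#'
#' @param sequence An [image_sequence()].
#' @param initial_region A [region()] in frame 0, positioned so the block
#'   search window fits inside the frame.
#' @param config A [tracker_config()].
#' @return A [track_trajectory()] with per-period diagnostics in
#'   `attr(, "periods")`.
#' @seealso [track_comparator()], [compare_methods()]
#' @export
track <- function(sequence, initial_region, config = tracker_config()) {
  stopifnot(inherits(sequence, "image_sequence"),
            inherits(initial_region, "region"))
  if (!region_inside(initial_region, sequence$height, sequence$width))
    stopf("initial region exceeds frame bounds")
  track_periods(sequence, initial_region, config, config$interpolation_mode)
}

#' Track with a comparator method
#'
#' * `of_only`: chained optical flow — [region_displacement()] on every
#'   adjacent frame pair, cumulatively summed (no block matching).
#' * `mkbm_only`: block matching on every adjacent frame pair with the
#'   template re-extracted each frame; integer displacements (no
#'   sub-pixel refinement), fused per `config$fusion` — use
#'   `fusion = "ncc"` for the original NCC-weighted multi-kernel
#'   baseline.  Drifts on sub-pixel motion.
#' * `adaptive_mkbm`: same flow periods and anchors as OFTB-MKBM, but
#'   intermediate frames interpolated linearly in frame index.
#'
#' @param sequence An [image_sequence()].
#' @param initial_region A [region()] in frame 0.
#' @param config A [tracker_config()].
#' @param method One of `"of_only"`, `"mkbm_only"`, `"adaptive_mkbm"`.
#' @return A [track_trajectory()].
#' @export
track_comparator <- function(sequence, initial_region,
                             config = tracker_config(),
                             method = c("of_only", "mkbm_only",
                                        "adaptive_mkbm")) {
  method <- match.arg(method)
  stopifnot(inherits(sequence, "image_sequence"),
            inherits(initial_region, "region"))
  n_frames <- length(sequence$frames)
  if (method == "adaptive_mkbm")
    return(track_periods(sequence, initial_region, config, "linear"))
  if (method == "mkbm_only") {
    # per-frame baseline matcher: integer matches only (sub-pixel
    # refinement is an extension of the combined tracker, not of the
    # block-matching baseline); fusion follows the config, with
    # fusion = "ncc" giving the original NCC-weighted variant
    config$refine_subpixel <- FALSE
  }
  cum_x <- numeric(n_frames); cum_y <- numeric(n_frames)
  prev_dir <- NULL
  last <- n_frames
  for (t in seq_len(n_frames - 1L)) {
    reg <- tryCatch(region_shift(initial_region, round(cum_x[t]),
                                 round(cum_y[t])),
                    error = function(e) NULL)
    if (is.null(reg) ||
        !region_inside(reg, sequence$height, sequence$width)) {
      warnf("track truncated at frame %d/%d (region reached the frame border)",
            t - 1L, n_frames - 1L)
      last <- t
      break
    }
    if (method == "of_only") {
      rd <- region_displacement(
        compute_flow_field(sequence$frames[[t]], sequence$frames[[t + 1L]],
                           reg, config),
        config, prev_direction = prev_dir)
      if (rd$direction %in% c("left", "right")) prev_dir <- rd$direction
      cum_x[t + 1L] <- cum_x[t] + rd$dx
      cum_y[t + 1L] <- cum_y[t] + rd$dy
    } else {                              # mkbm_only
      template <- block_template(sequence$frames[[t]], reg, frame_index = t - 1L)
      bd <- tryCatch(
        mkbm_displacement(template, sequence$frames[[t + 1L]],
                          predicted = c(0L, 0L), config = config),
        error = function(e) NULL)
      if (is.null(bd)) {
        warnf("track truncated at frame %d/%d (search window left the frame)",
              t - 1L, n_frames - 1L)
        last <- t
        break
      }
      cum_x[t + 1L] <- cum_x[t] + bd$dx
      cum_y[t + 1L] <- cum_y[t] + bd$dy
    }
  }
  idx <- seq_len(last)
  anchor <- if (method == "mkbm_only") rep(TRUE, last)
  else c(TRUE, rep(FALSE, last - 1L))
  track_trajectory(frame = idx - 1L, dx = cum_x[idx], dy = cum_y[idx],
                   is_anchor = anchor, method = method,
                   pixel_spacing = sequence$pixel_spacing,
                   frame_rate = sequence$frame_rate, config = config)
}
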