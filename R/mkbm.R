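# Multi-kernel block matching: the reference block is split into four
# overlapping sub-blocks, each matched independently by exhaustive
# sum-of-absolute-differences search, and the four results fused.  Using
# several kernels makes the match robust to local speckle variation;
# fusing by the maximum horizontal displacement rejects soft tissue that
# is passively dragged along with a smaller displacement than the tendon.

#' Mean sum of absolute differences between two blocks
#'
#' `sad(T, R) = sum(|T - R|) / (M*N)` for two `M x N` blocks.  Zero iff
#' the blocks are identical; symmetric; sensitive to intensity offsets
#' (unlike normalized cross-correlation).
#'
#' @param target,reference Numeric matrices of identical shape.
#' @return Non-negative scalar.
#' @export
sad <- function(target, reference) {
  if (!all(dim(target) == dim(reference)))
    stopf("sad: blocks differ in shape (%s vs %s)",
          paste(dim(target), collapse = "x"),
          paste(dim(reference), collapse = "x"))
  mean(abs(target - reference))
}

#' Extract a block template from a frame
#'
#' @param frame Numeric matrix.
#' @param reg A [region()] inside the frame.
#' @param frame_index 0-based source frame index (metadata).
#' @return A list of class `block_template` with `pixels`, `region`,
#'   `frame_index`.
#' @export
block_template <- function(frame, reg, frame_index = NA_integer_) {
  stopifnot(inherits(reg, "region"))
  if (!region_inside(reg, nrow(frame), ncol(frame)))
    stopf("template region exceeds frame bounds")
  structure(list(pixels = region_pixels(frame, reg), region = reg,
                 frame_index = frame_index),
            class = "block_template")
}

#' Split a block template into four overlapping sub-blocks
#'
#' The block is tiled 2 x 2; adjacent sub-blocks share exactly `overlap`
#' pixels in each dimension and their union is the full block.  With odd
#' block sizes the left/top sub-blocks take the extra pixel.
#'
#' @param template A [block_template()].
#' @param overlap Even overlap in pixels (default 10).
#' @return List of four sub-block descriptors (index 1 = top-left, 2 =
#'   top-right, 3 = bottom-left, 4 = bottom-right), each with `pixels`,
#'   `off_x`, `off_y` (0-based offset inside the block) and the absolute
#'   frame position `x`, `y` of its top-left corner.
#' @export
split_subblocks <- function(template, overlap = 10L) {
  stopifnot(inherits(template, "block_template"))
  overlap <- as.integer(overlap)
  if (overlap < 0L || overlap %% 2L != 0L)
    stopf("overlap must be even and >= 0")
  w <- template$region$width; h <- template$region$height
  if (w <= overlap + 2L || h <= overlap + 2L)
    stopf("block %d x %d too small for %d-px sub-block overlap", w, h, overlap)
  spans <- function(extent) {
    s <- as.integer(ceiling(extent / 2))     # split point; first part takes the extra pixel
    lo <- c(1L, s + overlap %/% 2L)          # 1-based [start, end] of first part
    hi <- c(s - overlap %/% 2L + 1L, extent)
    list(lo, hi)
  }
  xs <- spans(w); ys <- spans(h)
  out <- vector("list", 4L)
  k <- 0L
  for (iy in 1:2) for (ix in 1:2) {
    k <- k + 1L
    xr <- xs[[ix]]; yr <- ys[[iy]]
    out[[k]] <- list(index = k,
                     pixels = template$pixels[yr[1]:yr[2], xr[1]:xr[2],
                                              drop = FALSE],
                     off_x = xr[1] - 1L, off_y = yr[1] - 1L,
                     x = template$region$x + xr[1] - 1L,
                     y = template$region$y + yr[1] - 1L)
  }
  out
}

#' Match one sub-block in a target frame by exhaustive SAD search
#'
#' Evaluates the mean SAD at every integer displacement in
#' `predicted +/- search_range` and returns the minimizer.  Ties are
#' broken by smallest displacement magnitude, then smallest `dx`, then
#' smallest `dy`.  Candidates whose footprint leaves the frame are
#' dropped (with a warning when the search window is clipped).
#'
#' @param sub_block One element of [split_subblocks()].
#' @param target_frame Numeric matrix.
#' @param predicted `c(dx, dy)` integer displacement at which to centre
#'   the search (e.g. the optical-flow prediction).
#' @param search_range `c(x, y)` half-range in pixels.
#' @param refine When `TRUE`, refine the integer minimum to sub-pixel
#'   precision with the equiangular (V-shaped) fit
#'   `offset = (s- - s+) / (2 * (max(s-, s+) - s0))` along each axis,
#'   which is exact for an ideally translated block under SAD.  Off by
#'   default (integer matching).
#' @return A list of class `subblock_match` with `index`, `dx`, `dy`
#'   (pixels, relative to the sub-block's source position; integer unless
#'   `refine`) and `sad_score`.
#' @export
match_subblock <- function(sub_block, target_frame, predicted = c(0L, 0L),
                           search_range = c(20L, 10L), refine = FALSE) {
  dxs <- as.integer(round(predicted[1])) + seq.int(-search_range[1], search_range[1])
  dys <- as.integer(round(predicted[2])) + seq.int(-search_range[2], search_range[2])
  scores <- sad_search_cpp(target_frame, sub_block$pixels,
                           sub_block$y, sub_block$x, dys, dxs)
  if (anyNA(scores)) {
    if (all(is.na(scores)))
      stopf("search window for sub-block %d lies fully outside the frame",
            sub_block$index)
    warnf("search window for sub-block %d clipped at the frame border",
          sub_block$index)
  }
  grid_dx <- rep(dxs, each = length(dys))
  grid_dy <- rep(dys, times = length(dxs))
  sc <- as.vector(scores)
  keep <- !is.na(sc)
  o <- order(sc[keep], grid_dx[keep]^2 + grid_dy[keep]^2,
             grid_dx[keep], grid_dy[keep])[1]
  dx <- grid_dx[keep][o]; dy <- grid_dy[keep][o]
  dx_int <- dx; dy_int <- dy
  s0 <- sc[keep][o]
  if (refine) {
    i <- match(dy, dys); j <- match(dx, dxs)
    vfit <- function(sm, s0, sp) {
      den <- 2 * (max(sm, sp) - s0)
      if (!is.finite(den) || den <= 1e-12) return(0)
      max(-0.5, min(0.5, (sm - sp) / den))
    }
    if (j > 1L && j < length(dxs) &&
        is.finite(scores[i, j - 1L]) && is.finite(scores[i, j + 1L]))
      dx <- dx + vfit(scores[i, j - 1L], s0, scores[i, j + 1L])
    if (i > 1L && i < length(dys) &&
        is.finite(scores[i - 1L, j]) && is.finite(scores[i + 1L, j]))
      dy <- dy + vfit(scores[i - 1L, j], s0, scores[i + 1L, j])
  }
  structure(list(index = sub_block$index, dx = dx, dy = dy,
                 dx_int = dx_int, dy_int = dy_int, sad_score = s0),
            class = "subblock_match")
}

#' Fuse four sub-block matches into one block displacement
#'
#' The default `"magnitude"` rule keeps the sub-block with the largest
#' absolute horizontal displacement — the one least likely to belong to
#' passively dragged neighbouring tissue — and copies its signed
#' displacement.  `"signed"` keeps the algebraically largest `dx`.
#' Selection compares the integer search minima (`dx_int`); ties are
#' broken by lower SAD score, then lower sub-block index.  The fused
#' value is the selected sub-block's (possibly sub-pixel refined)
#' displacement.
#'
#' @param matches List of exactly four [match_subblock()] results.
#' @param mode `"magnitude"` or `"signed"`.
#' @return A list of class `block_displacement` with `dx`, `dy`,
#'   `contributing` (sub-block index) and `matches`.
#' @export
fuse_displacements <- function(matches, mode = c("magnitude", "signed")) {
  mode <- match.arg(mode)
  if (length(matches) != 4L) stopf("fusion needs exactly 4 sub-block matches")
  dx <- vapply(matches, function(m) m$dx_int %||% m$dx, numeric(1))
  score <- vapply(matches, `[[`, numeric(1), "sad_score")
  key <- if (mode == "magnitude") abs(dx) else dx
  o <- order(-key, score, seq_along(matches))[1]
  structure(list(dx = matches[[o]]$dx, dy = matches[[o]]$dy,
                 contributing = matches[[o]]$index, matches = matches),
            class = "block_displacement")
}

#' Multi-kernel block matching between a template and a target frame
#'
#' Splits the template into four overlapping sub-blocks, matches each by
#' exhaustive SAD search around the predicted displacement, and fuses the
#' four results.  The `"ncc"` fusion mode averages the four displacements
#' weighted by their normalized cross-correlation at the matched position
#' (the original multi-kernel fusion, yielding possibly fractional
#' displacements); `"magnitude"`/`"signed"` pass through
#' [fuse_displacements()].
#'
#' @param template A [block_template()].
#' @param target_frame Numeric matrix.
#' @param predicted `c(dx, dy)` displacement prediction.
#' @param config A [tracker_config()].
#' @return A `block_displacement`.
#' @export
mkbm_displacement <- function(template, target_frame, predicted = c(0L, 0L),
                              config = tracker_config()) {
  subs <- split_subblocks(template, config$subblock_overlap)
  matches <- lapply(subs, match_subblock, target_frame = target_frame,
                    predicted = predicted, search_range = config$search_range,
                    refine = isTRUE(config$refine_subpixel))
  if (config$fusion == "ncc") {
    w <- vapply(seq_along(subs), function(i) {
      sb <- subs[[i]]; mm <- matches[[i]]
      mdx <- round(mm$dx); mdy <- round(mm$dy)
      tgt <- target_frame[(sb$y + mdy + 1L):(sb$y + mdy + nrow(sb$pixels)),
                          (sb$x + mdx + 1L):(sb$x + mdx + ncol(sb$pixels)),
                          drop = FALSE]
      if (sd(tgt) < 1e-12 || sd(sb$pixels) < 1e-12) return(0)
      max(cor(as.vector(tgt), as.vector(sb$pixels)), 0)
    }, numeric(1))
    if (sum(w) < 1e-12) w <- rep(1, 4L)
    dx <- vapply(matches, `[[`, numeric(1), "dx")
    dy <- vapply(matches, `[[`, numeric(1), "dy")
    structure(list(dx = sum(w * dx) / sum(w), dy = sum(w * dy) / sum(w),
                   contributing = which.max(w), matches = matches),
              class = "block_displacement")
  } else {
    fuse_displacements(matches, mode = config$fusion)
  }
}

#' @export
print.block_displacement <- function(x, ...) {
  cat(sprintf("block_displacement: (%.2f, %.2f) px from sub-block %d\n",
              x$dx, x$dy, x$contributing))
  invisible(x)
}
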