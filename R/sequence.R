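#' Construct an image sequence
#'
#' An `image_sequence` is an ordered list of single-channel frames sharing
#' one geometry, with the physical metadata needed to convert pixel
#' displacements to millimetres and frames to seconds.
#'
#' @param frames List of numeric matrices (rows = image y/depth, columns =
#'   image x/lateral), all the same size, intensities in `[0, 1]`.
#' @param pixel_spacing Pixel size in mm/pixel.  A single value (isotropic)
#'   or `c(x, y)`.
#' @param frame_rate Frames per second.
#' @return An object of class `image_sequence`: a list with elements
#'   `frames`, `pixel_spacing`, `frame_rate`, `width`, `height`.
#' @seealso [load_sequence()], [render_sequence()]
#' @export
image_sequence <- function(frames, pixel_spacing = NA_real_, frame_rate = NA_real_) {
  if (!is.list(frames) || length(frames) < 2L)
    stopf("an image sequence needs at least 2 frames (got %d)", length(frames))
  if (!all(vapply(frames, is.matrix, logical(1))))
    stopf("all frames must be numeric matrices")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("frames have inconsistent sizes")
  if (!all(vapply(frames, function(f) all(is.finite(f)), logical(1))))
    stopf("frame intensities must be finite")
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  structure(list(frames = frames,
                 pixel_spacing = as.numeric(pixel_spacing),
                 frame_rate = as.numeric(frame_rate),
                 height = dims[1, 1], width = dims[2, 1]),
            class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  cat(sprintf("image_sequence: %d frames of %d x %d px\n",
              length(x$frames), x$width, x$height))
  cat(sprintf("  pixel spacing: %s mm/px, frame rate: %s fps\n",
              paste(signif(x$pixel_spacing, 4), collapse = " x "),
              format(x$frame_rate)))
  invisible(x)
}

#' @export
length.image_sequence <- function(x) length(x$frames)

#' Define a rectangular tracking region
#'
#' Regions are axis-aligned rectangles anchored at their top-left corner,
#' using 0-based pixel coordinates with x increasing rightward (the lateral
#' / tendon axis) and y increasing downward (depth).
#'
#' @param x,y Top-left corner, 0-based pixels.
#' @param width,height Size in pixels (each at least 3).
#' @return An object of class `region`.
#' @export
region <- function(x, y, width, height) {
  x <- as.integer(x); y <- as.integer(y)
  width <- as.integer(width); height <- as.integer(height)
  if (width < 3L || height < 3L)
    stopf("region must be at least 3 x 3 px (got %d x %d)", width, height)
  if (x < 0L || y < 0L) stopf("region corner must be non-negative")
  structure(list(x = x, y = y, width = width, height = height),
            class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("region: %d x %d px at (%d, %d)\n", x$width, x$height, x$x, x$y))
  invisible(x)
}

# TRUE when the region lies fully inside a height x width frame,
# optionally inflated by margin = c(mx, my) pixels on every side.
region_inside <- function(reg, height, width, margin = c(0L, 0L)) {
  reg$x - margin[1] >= 0L && reg$y - margin[2] >= 0L &&
    reg$x + reg$width + margin[1] <= width &&
    reg$y + reg$height + margin[2] <= height
}

# Shift a region by integer (dx, dy).
region_shift <- function(reg, dx, dy) {
  region(reg$x + as.integer(round(dx)), reg$y + as.integer(round(dy)),
         reg$width, reg$height)
}

# Extract region pixels from a frame (1-based matrix indexing internally).
region_pixels <- function(frame, reg) {
  frame[(reg$y + 1L):(reg$y + reg$height),
        (reg$x + 1L):(reg$x + reg$width), drop = FALSE]
}
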