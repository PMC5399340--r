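#' Read a grayscale image sequence
#'
#' Supported containers: a multi-page TIFF file, or a directory of
#' single-frame PNG/TIFF images ordered by file name.  Color frames are
#' converted to luminance (Rec. 601 weights) and intensities are rescaled
#' into `[0, 1]`.
#'
#' Compressed video containers (AVI/MP4) are not decoded directly; convert
#' them to a TIFF stack or a PNG frame directory first (e.g. with ffmpeg:
#' `ffmpeg -i in.avi frames/%04d.png`).
#'
#' @param path Path to a `.tif`/`.tiff` stack or a frame directory.
#' @param pixel_spacing mm/pixel (scalar or `c(x, y)`).
#' @param frame_rate Frames per second.
#' @return An [image_sequence()].
#' @export
load_sequence <- function(path, pixel_spacing = NA_real_, frame_rate = NA_real_) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- files[order(basename(files))]
    if (length(files) < 2L)
      stopf("frame directory %s holds %d readable frame(s); need at least 2",
            path, length(files))
    frames <- lapply(files, read_one_frame)
  } else if (file.exists(path)) {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("tif", "tiff")) {
      pages <- tiff::readTIFF(path, all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      if (length(pages) < 2L)
        stopf("%s holds %d frame(s); need at least 2", path, length(pages))
      frames <- lapply(pages, to_luminance)
    } else if (ext %in% c("avi", "mp4", "mov", "mkv")) {
      stopf(paste("video container %s is not decoded directly;",
                  "convert it to a multi-page TIFF or a PNG frame",
                  "directory first"), path)
    } else {
      stopf("unsupported sequence format: %s", path)
    }
  } else {
    stopf("cannot read sequence: %s does not exist", path)
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("frames in %s have inconsistent sizes", path)
  image_sequence(frames, pixel_spacing = pixel_spacing, frame_rate = frame_rate)
}

read_one_frame <- function(file) {
  ext <- tolower(tools::file_ext(file))
  img <- if (ext == "png") png::readPNG(file) else tiff::readTIFF(file)
  to_luminance(img)
}

# Collapse color/alpha planes to Rec. 601 luminance; clamp into [0,1].
to_luminance <- function(img) {
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    img <- if (nc >= 3L)
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    else img[, , 1]
  }
  img <- as.matrix(img)
  if (max(img) > 1) img <- img / max(img)
  pmin(pmax(img, 0), 1)
}

#' Write an image sequence as a multi-page TIFF
#'
#' Frames are stored as 32-bit floating point samples, so a read-back with
#' [load_sequence()] reproduces intensities to single precision.
#'
#' @param sequence An [image_sequence()].
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
save_sequence <- function(sequence, path) {
  stopifnot(inherits(sequence, "image_sequence"))
  tiff::writeTIFF(sequence$frames, path, bits.per.sample = 32)
  invisible(path)
}

#' Write a trajectory to CSV
#'
#' Columns: `frame` (0-based), `dx_px`, `dy_px` (cumulative displacement
#' relative to frame 0), `ddx_px`, `ddy_px` (frame-to-frame delta) and
#' `is_anchor` (TRUE where a flow period ended and block matching was
#' applied).  Values are written with full double precision; a round trip
#' through [load_trajectory()] reproduces them to better than 1e-9.
#'
#' @param trajectory A [track_trajectory()] or compatible data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
save_trajectory <- function(trajectory, path) {
  df <- as.data.frame(trajectory)
  need <- c("frame", "dx_px", "dy_px", "ddx_px", "ddy_px", "is_anchor")
  if (!all(need %in% names(df)))
    stopf("trajectory lacks column(s): %s",
          paste(setdiff(need, names(df)), collapse = ", "))
  if (nrow(df) == 0L) stopf("refusing to write an empty trajectory")
  out <- df[, need]
  for (cc in c("dx_px", "dy_px", "ddx_px", "ddy_px"))
    out[[cc]] <- formatC(out[[cc]], format = "g", digits = 17)
  ok <- tryCatch({ write.csv(out, path, row.names = FALSE, quote = FALSE); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) stopf("cannot write trajectory to %s: %s", path,
                         conditionMessage(ok))
  invisible(path)
}

#' Read a trajectory CSV
#'
#' Accepts the full format written by [save_trajectory()] or a bare
#' two-column `(frame, x)` file of cumulative horizontal positions, as
#' produced by manual point tracking; in the latter case deltas are
#' derived and `dy` is set to zero.
#'
#' @param path CSV path.
#' @return A [track_trajectory()].
#' @export
load_trajectory <- function(path) {
  if (!file.exists(path)) stopf("trajectory file not found: %s", path)
  df <- read.csv(path)
  if (all(c("frame", "dx_px", "dy_px", "ddx_px", "ddy_px", "is_anchor") %in%
          names(df))) {
    track_trajectory(frame = df$frame, dx = df$dx_px, dy = df$dy_px,
                     is_anchor = as.logical(df$is_anchor))
  } else if (ncol(df) >= 2L) {
    x <- df[[2]] - df[[2]][1]
    track_trajectory(frame = df[[1]], dx = x, dy = rep(0, length(x)),
                     is_anchor = c(TRUE, rep(FALSE, length(x) - 2L), TRUE))
  } else {
    stopf("%s is neither a trajectory CSV nor a (frame, x) table", path)
  }
}

#' Write a JSON run report
#'
#' Echoes the configuration and summarizes each flow period (start frame,
#' length, accumulated displacement, per-pair Va and N, contributing
#' sub-block) of a tracked trajectory.
#'
#' @param trajectory A [track_trajectory()] produced by [track()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_run_report <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "track_trajectory"))
  cfg <- attr(trajectory, "config")
  if (!is.null(cfg)) {
    cfg <- unclass(cfg)
    cfg$va_n_table <- list(va = cfg$va_n_table$va,
                           n_percent = cfg$va_n_table$n_percent)
  }
  rep <- list(method = attr(trajectory, "method"),
              n_frames = nrow(trajectory),
              anchor_frames = trajectory$frame[trajectory$is_anchor],
              total_dx_px = trajectory$dx_px[nrow(trajectory)],
              config = cfg,
              periods = attr(trajectory, "periods"))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
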