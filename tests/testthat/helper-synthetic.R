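# Shared fixtures, all generated in code.

# Smooth band-limited test image sampled from an analytic function, so it
# can be evaluated at arbitrary sub-pixel shifts.
smooth_fun <- function(x, y) {
  0.5 + 0.2 * sin(2 * pi * x / 24) + 0.15 * sin(2 * pi * y / 20) +
    0.1 * sin(2 * pi * (x + y) / 30)
}

smooth_image <- function(width = 150, height = 80, shift = 0) {
  outer(0:(height - 1), 0:(width - 1), function(y, x) smooth_fun(x - shift, y))
}

# One noise-free speckle frame (for matching tests).
speckle_frame <- function(width = 260, height = 140, seed = 42,
                          noise_sd = 0, rho = 0) {
  sp <- phantom_spec(frame_size = c(width, height),
                     motion = motion_profile("piecewise", n_frames = 2,
                                             dx = c(0, 0)),
                     noise_sd = noise_sd, rho = rho, seed = seed)
  render_sequence(sp)$sequence$frames[[1]]
}

# Translate a matrix by integer (dx, dy) with replicate edges: the content
# moves right/down for positive shifts.
shift_matrix <- function(m, dx, dy) {
  h <- nrow(m); w <- ncol(m)
  rows <- pmin(pmax(seq_len(h) - dy, 1L), h)
  cols <- pmin(pmax(seq_len(w) - dx, 1L), w)
  m[rows, cols, drop = FALSE]
}

# Construct a flow_field by hand from velocity vectors (for reduction and
# calibration tests); lays values out on an arbitrary grid.
make_flow_field <- function(vx, vy = rep(0, length(vx)),
                            valid = rep(TRUE, length(vx))) {
  n <- length(vx)
  structure(list(vx = matrix(vx, nrow = 1), vy = matrix(vy, nrow = 1),
                 valid = matrix(valid, nrow = 1),
                 gx = seq_len(n) - 1L, gy = 0L,
                 region = region(0, 0, max(3, n), 3)),
            class = "flow_field")
}

# Independent naive exhaustive SAD search (pure R double loop), with the
# same tie-break rules as the matcher under test.
naive_match <- function(tmpl, ty, tx, target, pred, range) {
  rows <- list()
  for (dx in (pred[1] - range[1]):(pred[1] + range[1])) {
    for (dy in (pred[2] - range[2]):(pred[2] + range[2])) {
      y0 <- ty + dy; x0 <- tx + dx
      if (y0 < 0 || x0 < 0 || y0 + nrow(tmpl) > nrow(target) ||
          x0 + ncol(tmpl) > ncol(target)) next
      s <- mean(abs(target[(y0 + 1):(y0 + nrow(tmpl)),
                           (x0 + 1):(x0 + ncol(tmpl))] - tmpl))
      rows[[length(rows) + 1L]] <- c(s, dx^2 + dy^2, dx, dy)
    }
  }
  m <- do.call(rbind, rows)
  best <- m[order(m[, 1], m[, 2], m[, 3], m[, 4])[1], ]
  list(dx = best[3], dy = best[4], sad_score = best[1])
}

# Wrap a raw pixel block as a sub_block descriptor at frame position (x, y).
as_subblock <- function(pixels, x, y, index = 1L) {
  list(index = index, pixels = pixels, off_x = 0L, off_y = 0L, x = x, y = y)
}
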