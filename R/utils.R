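# Internal numerical helpers shared across modules.

# 1-D Gaussian kernel, truncated at 3 sigma, normalized.
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Separable Gaussian blur with replicate (edge-clamp) padding.
# sigma_x smooths along columns (image x / width), sigma_y along rows.
gaussian_blur <- function(m, sigma_x, sigma_y = sigma_x) {
  if (sigma_x <= 0 && sigma_y <= 0) return(m)
  conv_cols <- function(mat, k) {
    r <- (length(k) - 1L) / 2L
    if (r == 0L) return(mat)
    nr <- nrow(mat)
    pad <- rbind(mat[rep(1L, r), , drop = FALSE], mat,
                 mat[rep(nr, r), , drop = FALSE])
    # stats::filter runs the kernel down each column
    out <- stats::filter(pad, k, sides = 2)
    matrix(out[(r + 1L):(r + nr), ], nrow = nr)
  }
  if (sigma_y > 0) m <- conv_cols(m, gauss_kernel(sigma_y))
  if (sigma_x > 0) m <- t(conv_cols(t(m), gauss_kernel(sigma_x)))
  m
}

# Crop rows y0..y1, cols x0..x1 (1-based, may exceed bounds) with
# replicate padding outside the frame.
crop_pad <- function(frame, y0, y1, x0, x1) {
  ry <- pmin(pmax(y0:y1, 1L), nrow(frame))
  rx <- pmin(pmax(x0:x1, 1L), ncol(frame))
  frame[ry, rx, drop = FALSE]
}

# Summed-area table with a zero first row/column so that the sum over
# rows a..b, cols c..d is S[b+1,d+1] - S[a,d+1] - S[b+1,c] + S[a,c].
integral_image <- function(m) {
  s <- apply(m, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  rbind(0, cbind(0, s))
}

# Window sums of m over (2r+1)x(2r+1) windows centred at every (cy, cx)
# combination.  Returns a length(cy) x length(cx) matrix.
window_sums <- function(m, cy, cx, r) {
  s <- integral_image(m)
  a <- cy - r; b <- cy + r; cc <- cx - r; d <- cx + r
  s[b + 1L, d + 1L, drop = FALSE] - s[a, d + 1L, drop = FALSE] -
    s[b + 1L, cc, drop = FALSE] + s[a, cc, drop = FALSE]
}

# Evaluate an expression with a private RNG stream seeded by `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
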