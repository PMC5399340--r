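test_that("period interpolation matches the anchors exactly", {
  out <- interpolate_period(c(0, 1, 2), d_start = 0, d_end = 3)
  expect_equal(out[1], 0)
  expect_equal(out[3], 3)
  expect_equal(out[2], 1.5)                 # 0 + 1 * (3 - 0) / 2
  expect_false(attr(out, "fallback"))
  # anchors carry through arbitrary offsets
  out2 <- interpolate_period(c(0, 0.4, 1.1, 1.9), d_start = -2.5, d_end = 4.25)
  expect_equal(out2[1], -2.5)
  expect_equal(out2[4], 4.25)
})

test_that("degenerate flow trends fall back to linear interpolation", {
  out <- interpolate_period(c(0, 0.5, 0), d_start = 1, d_end = 3)
  expect_true(attr(out, "fallback"))
  expect_equal(as.numeric(out), c(1, 2, 3))
  lin <- interpolate_period(c(0, 0.2, 1.8, 2), d_start = 0, d_end = 6,
                            mode = "linear")
  expect_equal(as.numeric(lin), c(0, 2, 4, 6))
  expect_false(attr(lin, "fallback"))
})

test_that("interpolation preserves monotonicity of the flow trend", {
  set.seed(20)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    dof <- cumsum(c(0, runif(n, 0, 2)))
    d_end <- runif(1, 0.5, 15)
    out <- interpolate_period(dof, 0, d_end)
    expect_true(all(diff(out) >= -1e-12))
  }
})

test_that("accumulation stops when |Da| reaches lambda", {
  r <- render_sequence(phantom_spec(
    frame_size = c(240L, 120L),
    motion = motion_profile("constant_velocity", n_frames = 12, vx = 0),
    noise_sd = 0, rho = 0, seed = 21))
  const2 <- function(seq, pair, reg, cfg, prev)
    structure(list(dx = 2, dy = 0, direction = "right", n_points_used = 10L,
                   va = 2, n_percent = 50, degenerate = FALSE),
              class = "region_displacement")
  per <- accumulate_until_threshold(r$sequence, 0, region(60, 40, 101, 41),
                                    tracker_config(lambda_px = 10),
                                    flow_fn = const2)
  expect_equal(per$end - per$start, 5L)     # 5 x 2 px = 10 >= lambda
  expect_equal(per$da, 10)
  expect_equal(per$dof_x, c(0, 2, 4, 6, 8, 10))
  # leftward motion triggers on |Da|
  constm <- function(seq, pair, reg, cfg, prev)
    structure(list(dx = -3, dy = 0, direction = "left", n_points_used = 10L,
                   va = 3, n_percent = 50, degenerate = FALSE),
              class = "region_displacement")
  perm <- accumulate_until_threshold(r$sequence, 0, region(60, 40, 101, 41),
                                     tracker_config(lambda_px = 9),
                                     flow_fn = constm)
  expect_equal(perm$end - perm$start, 3L)
  expect_equal(perm$da, -9)
})

test_that("a period ends at the sequence end when Da never reaches lambda", {
  r <- render_sequence(phantom_spec(
    frame_size = c(240L, 120L),
    motion = motion_profile("constant_velocity", n_frames = 7, vx = 0),
    noise_sd = 0, rho = 0, seed = 22))
  const1 <- function(seq, pair, reg, cfg, prev)
    structure(list(dx = 1, dy = 0, direction = "right", n_points_used = 10L,
                   va = 1, n_percent = 50, degenerate = FALSE),
              class = "region_displacement")
  per <- accumulate_until_threshold(r$sequence, 0, region(60, 40, 101, 41),
                                    tracker_config(lambda_px = 10),
                                    flow_fn = const1)
  expect_equal(per$end, 6L)                 # last frame, 0-based
  expect_equal(per$da, 6)                   # < lambda: ran out of frames
  expect_false(per$truncated)
})

test_that("a static sequence tracks to an identically zero trajectory", {
  r <- render_sequence(phantom_spec(
    frame_size = c(240L, 120L),
    motion = motion_profile("constant_velocity", n_frames = 10, vx = 0),
    noise_sd = 0, rho = 0, seed = 23))
  tr <- track(r$sequence, region(60, 40, 101, 41))
  expect_equal(nrow(tr), 10L)
  expect_true(all(tr$dx_px == 0))
  expect_true(all(tr$dy_px == 0))
  expect_length(attr(tr, "periods"), 1L)    # one period spanning everything
  expect_true(tr$is_anchor[10])             # final frame is an anchor
})

test_that("constant-velocity speckle is tracked within 5% of the truth", {
  r <- render_sequence(phantom_spec(
    frame_size = c(400L, 200L),
    motion = motion_profile("constant_velocity", n_frames = 120, vx = 0.5),
    noise_sd = 0.02, rho = 0.02, seed = 3))
  tr <- track(r$sequence, region(40, 80, 101, 41))
  expect_equal(nrow(tr), 120L)
  truth <- r$motion$dx[120]
  expect_lt(abs(tr$dx_px[120] - truth) / truth, 0.05)
})

test_that("anchor frames carry the cumulative fused block displacement", {
  r <- render_sequence(phantom_spec(
    frame_size = c(300L, 150L),
    motion = motion_profile("constant_velocity", n_frames = 40, vx = 1),
    noise_sd = 0.01, rho = 0.01, seed = 24))
  tr <- track(r$sequence, region(40, 50, 101, 41))
  cum <- 0
  for (p in attr(tr, "periods")) {
    cum <- cum + p$d_mkbm[1]
    anchor_frame <- p$start + p$n
    expect_equal(tr$dx_px[anchor_frame + 1L], cum)
  }
  expect_true(tr$is_anchor[nrow(tr)])
})

test_that("with lambda near zero the tracker degenerates to per-frame MKBM", {
  r <- render_sequence(phantom_spec(
    frame_size = c(300L, 150L),
    motion = motion_profile("constant_velocity", n_frames = 30, vx = 1.5),
    noise_sd = 0.01, rho = 0.01, seed = 9))
  roi <- region(60, 50, 101, 41)
  t_oftb <- track(r$sequence, roi, tracker_config(lambda_px = 1e-9))
  t_mkbm <- track_comparator(r$sequence, roi, tracker_config(), "mkbm_only")
  expect_equal(t_oftb$dx_px, t_mkbm$dx_px)
  expect_equal(t_oftb$dy_px, t_mkbm$dy_px)
  expect_true(all(t_oftb$is_anchor))
})

test_that("tracking is deterministic", {
  r <- render_sequence(phantom_spec(
    frame_size = c(300L, 150L),
    motion = motion_profile("constant_velocity", n_frames = 25, vx = 1),
    noise_sd = 0.02, rho = 0.02, seed = 25))
  roi <- region(60, 50, 101, 41)
  t1 <- track(r$sequence, roi)
  t2 <- track(r$sequence, roi)
  expect_identical(t1$dx_px, t2$dx_px)
  expect_identical(t1$dy_px, t2$dy_px)
})

test_that("direction reversals are tracked through the turning point", {
  r <- render_sequence(tendon_analog_spec("triangle", amplitude = 30,
                                          period = 60, n_frames = 70,
                                          seed = 4))
  roi <- region(150, 80, 101, 41)
  tr <- track(r$sequence, roi)
  peak_pred <- tr$frame[which.max(tr$dx_px)]
  peak_true <- r$motion$frame[which.max(r$motion$dx)]
  expect_lte(abs(peak_pred - peak_true), 2)
})

test_that("adaptive-MKBM shares anchors with the tracker but not interiors", {
  r <- render_sequence(phantom_spec(
    frame_size = c(300L, 150L),
    motion = motion_profile("piecewise", n_frames = 9,
                            dx = c(0, 0.1, 0.2, 2.5, 4.8, 5.0, 5.1, 7.0, 9.5)),
    noise_sd = 0.01, rho = 0, seed = 26))
  roi <- region(60, 50, 101, 41)
  cfg <- tracker_config(lambda_px = 8)
  t_of <- track(r$sequence, roi, cfg)
  t_ad <- track_comparator(r$sequence, roi, cfg, "adaptive_mkbm")
  expect_equal(t_of$is_anchor, t_ad$is_anchor)
  anchors <- which(t_of$is_anchor)
  expect_equal(t_of$dx_px[anchors], t_ad$dx_px[anchors])
  # strongly non-uniform flow: interiors must differ somewhere
  expect_gt(max(abs(t_of$dx_px - t_ad$dx_px)), 0.2)
})

test_that("per-frame MKBM drifts more than OFTB-MKBM on sub-pixel motion", {
  r <- render_sequence(phantom_spec(
    frame_size = c(300L, 150L),
    motion = motion_profile("constant_velocity", n_frames = 60, vx = 0.25),
    noise_sd = 0.02, rho = 0.02, seed = 27))
  roi <- region(60, 50, 101, 41)
  cfg <- tracker_config(lambda_px = 3)
  t_of <- track(r$sequence, roi, cfg)
  t_mk <- track_comparator(r$sequence, roi, cfg, "mkbm_only")
  truth <- r$motion$dx[60]
  expect_lt(abs(t_of$dx_px[60] - truth), abs(t_mk$dx_px[60] - truth))
})

test_that("a region drifting off the frame truncates the track with a warning", {
  r <- render_sequence(phantom_spec(
    frame_size = c(220L, 120L),
    motion = motion_profile("constant_velocity", n_frames = 40, vx = 4),
    noise_sd = 0, rho = 0, seed = 28))
  ws <- capture_warnings(tr <- track(r$sequence, region(100, 38, 101, 41)))
  expect_true(any(grepl("truncated", ws)))
  expect_lt(nrow(tr), 40L)
  expect_gt(nrow(tr), 1L)
})
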