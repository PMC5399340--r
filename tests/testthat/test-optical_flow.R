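test_that("flow on identical frames is exactly zero at every valid point", {
  img <- speckle_frame(200, 120, seed = 1)
  ff <- compute_flow_field(img, img, region(40, 30, 101, 41))
  expect_true(all(ff$valid))
  expect_true(all(ff$vx == 0))
  expect_true(all(ff$vy == 0))
  fp <- lucas_kanade_point(img, img, center = c(90, 60))
  expect_identical(c(fp$vx, fp$vy), c(0, 0))
})

test_that("a unit translation of a smooth image is recovered", {
  img0 <- smooth_image()
  img1 <- smooth_image(shift = 1)
  fp <- lucas_kanade_point(img0, img1, center = c(75, 40), window = 17)
  expect_true(fp$valid)
  expect_lt(abs(fp$vx - 1), 0.05)
  expect_lt(abs(fp$vy), 0.05)
})

test_that("textureless windows are flagged invalid", {
  flat <- matrix(0.5, 80, 120)
  fp <- lucas_kanade_point(flat, flat, center = c(60, 40))
  expect_false(fp$valid)
  expect_true(is.na(fp$vx))
  expect_error(lucas_kanade_point(flat, flat, center = c(2, 2)), "bounds")
})

test_that("default region geometry yields a 43 x 13 grid of 559 points", {
  img <- speckle_frame(220, 120, seed = 2)
  ff <- compute_flow_field(img, img, region(40, 30, 101, 41))
  expect_length(ff$gx, 43L)
  expect_length(ff$gy, 13L)
  expect_equal(length(ff$vx), 559L)
  # grid nodes stay inside the region with the half-window margin
  expect_true(all(ff$gx >= 40 + 8 & ff$gx <= 40 + 100 - 8))
  expect_true(all(ff$gy >= 30 + 8 & ff$gy <= 30 + 40 - 8))
  expect_error(compute_flow_field(img, img, region(0, 0, 10, 10)),
               "too small")
})

test_that("flow is equivariant under a common integer shift of both frames", {
  big0 <- smooth_image(200, 120)
  big1 <- smooth_image(200, 120, shift = 0.6)
  off <- c(7L, 5L)
  ff_a <- compute_flow_field(big0, big1, region(40, 30, 101, 41))
  ff_b <- compute_flow_field(shift_matrix(big0, off[1], off[2]),
                             shift_matrix(big1, off[1], off[2]),
                             region(40 + off[1], 30 + off[2], 101, 41))
  expect_equal(ff_a$vx, ff_b$vx, tolerance = 1e-10)
  expect_equal(ff_a$vy, ff_b$vy, tolerance = 1e-10)
})

test_that("point-wise and field solvers agree at grid nodes", {
  img0 <- speckle_frame(200, 120, seed = 3)
  img1 <- 0.6 * img0 + 0.4 * speckle_frame(200, 120, seed = 4)
  ff <- compute_flow_field(img0, img1, region(50, 35, 45, 25))
  for (i in c(1L, 3L)) for (j in c(1L, 8L)) {
    fp <- lucas_kanade_point(img0, img1, c(ff$gx[j], ff$gy[i]))
    if (fp$valid) {
      expect_equal(fp$vx, ff$vx[i, j], tolerance = 1e-8)
      expect_equal(fp$vy, ff$vy[i, j], tolerance = 1e-8)
    }
  }
})

test_that("horizontal direction voting follows the sign of vx", {
  expect_identical(classify_direction(-0.3), "left")
  expect_identical(classify_direction(0.7), "right")
  expect_identical(classify_direction(0), "ignored")
  expect_identical(classify_direction(c(-1, 0, 2)),
                   c("left", "ignored", "right"))
  expect_error(classify_direction(NaN))
})

test_that("region displacement averages the top-N retained flow points", {
  # 10 rightward points; forcing N = 30% keeps ceil(3) = 3 points
  ff <- make_flow_field(seq(2.0, 0.2, by = -0.2))
  rd <- region_displacement(ff, tracker_config(), n_override = 30)
  expect_equal(rd$dx, mean(c(2.0, 1.8, 1.6)))
  expect_equal(rd$n_points_used, 3L)
  expect_identical(rd$direction, "right")
  # identical velocities: any N gives the common value
  ff2 <- make_flow_field(rep(0.7, 20))
  for (n in c(5, 30, 100))
    expect_equal(region_displacement(ff2, n_override = n)$dx, 0.7)
})

test_that("the default calibration table maps Va = 1.5 px to N = 20%", {
  expect_equal(lookup_n(va_n_table(), 1.5), 20)
  # clamped outside the knot range
  expect_equal(lookup_n(va_n_table(), 0.1), 60)
  expect_equal(lookup_n(va_n_table(), 9), 5)
  expect_error(va_n_table(c(1, 1), c(10, 10)), "increasing")
  expect_error(va_n_table(1.5, 0), "0, 100")
})

test_that("region displacement is invariant to flow-point order", {
  set.seed(7)
  vx <- rnorm(200, 0.8, 0.5)
  vy <- rnorm(200, 0, 0.2)
  rd1 <- region_displacement(make_flow_field(vx, vy))
  p <- sample.int(200)
  rd2 <- region_displacement(make_flow_field(vx[p], vy[p]))
  expect_equal(rd1$dx, rd2$dx)
  expect_equal(rd1$dy, rd2$dy)
  expect_equal(rd1$va, rd2$va)
})

test_that("majority vote retains the dominant direction and handles ties", {
  rd <- region_displacement(make_flow_field(c(-1, -2, -3, 0.5)))
  expect_identical(rd$direction, "left")
  # exact tie without history: direction none, zero displacement
  tie <- make_flow_field(c(-1, -2, 1, 2))
  rd0 <- region_displacement(tie)
  expect_identical(rd0$direction, "none")
  expect_equal(rd0$dx, 0)
  expect_true(rd0$degenerate)
  # tie broken by the previous pair's direction
  rdp <- region_displacement(tie, prev_direction = "right")
  expect_identical(rdp$direction, "right")
  expect_gt(rdp$dx, 0)
  # all invalid
  rdi <- region_displacement(make_flow_field(c(1, 1), valid = c(FALSE, FALSE)))
  expect_identical(rdi$direction, "none")
})

test_that("sub-pixel global translations are recovered within 0.1 px", {
  img0 <- smooth_image()
  reg <- region(25, 20, 101, 41)
  for (s in c(-1, -0.5, -0.25, 0.25, 0.5, 1)) {
    rd <- region_displacement(compute_flow_field(img0, smooth_image(shift = s),
                                                 reg))
    expect_lt(abs(rd$dx - s), 0.1)
  }
})

test_that("large speckle translations are underestimated", {
  sp <- phantom_spec(frame_size = c(300L, 150L),
                     motion = motion_profile("piecewise", n_frames = 2,
                                             dx = c(0, 6)),
                     noise_sd = 0, rho = 0, seed = 6)
  r <- render_sequence(sp)
  rd <- region_displacement(
    compute_flow_field(r$sequence$frames[[1]], r$sequence$frames[[2]],
                       region(90, 50, 101, 41)))
  expect_identical(rd$direction, "right")
  expect_lt(abs(rd$dx), 6)
})

test_that("calibration recovers the generating percentage", {
  # strictly decreasing magnitudes with unit gaps: the top-k mean matches
  # the truth only at one k, so the smallest matching N is unique
  m <- 559
  base <- seq(m + 40, 41)                 # 599 .. 41, all rightward
  k5 <- ceiling(0.05 * m)                 # 28 points
  recs5 <- lapply(1:12, function(i)
    list(flow_field = make_flow_field(base + i / 10),
         gt_dx = mean((base + i / 10)[1:k5])))
  tab5 <- calibrate_va_n(recs5)
  expect_true(all(abs(tab5$n_percent - 5) < 1e-9))

  k50 <- ceiling(0.50 * m)
  recs50 <- lapply(1:12, function(i)
    list(flow_field = make_flow_field(base + i / 10),
         gt_dx = mean((base + i / 10)[1:k50])))
  tab50 <- calibrate_va_n(recs50)
  expect_true(all(abs(tab50$n_percent - 50) < 5))

  expect_error(calibrate_va_n(recs5[1:5]), "at least 10")
})

test_that("calibration knots increase strictly in Va", {
  set.seed(11)
  recs <- lapply(1:40, function(i) {
    scale <- 0.5 + 2.5 * (i - 1) / 39
    vx <- scale * (1 + 0.3 * rnorm(559))
    list(flow_field = make_flow_field(vx), gt_dx = scale)
  })
  tab <- calibrate_va_n(recs)
  expect_gte(length(tab$va), 2L)
  expect_true(all(diff(tab$va) > 0))
  expect_true(all(diff(tab$n_percent) <= 0))
})
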