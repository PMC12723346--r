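# Stage calibration, navigation, deformation metrics.

test_that("two-anchor similarity calibration is exact", {
  m <- calibrate(anchors(c(0, 1), c(0, 0), c(0, 500), c(0, 0)), 500)
  expect_equal(m$theta_deg, 0)
  expect_equal(m$scale, 1)
  expect_equal(c(m$tx, m$ty), c(0, 0))
  expect_equal(m$rms_residual, 0)

  m90 <- calibrate(anchors(c(0, 1), c(0, 0), c(0, 0), c(0, 500)), 500)
  expect_equal(m90$theta_deg, 90)
  expect_equal(m90$scale, 1)
  expect_equal(grid_to_stage(m90, c(0, 1)), c(-500, 0), tolerance = 1e-12)

  # forward-synthesised stretch + rotation recovered to machine precision
  th <- 12 * pi / 180
  m2 <- calibrate(anchors(c(0, 2), c(0, 0),
                          c(10, 10 + 1100 * cos(th)), c(20, 20 + 1100 * sin(th))), 500)
  expect_equal(m2$scale, 1.1, tolerance = 1e-9)
  expect_equal(m2$theta_deg, 12, tolerance = 1e-9)
})

test_that("random similarity transforms are recovered to 1e-9 relative error", {
  set.seed(5)
  for (k in 1:50) {
    th <- runif(1, 0, 2 * pi)
    s <- runif(1, 0.5, 2)
    t <- runif(2, -1e4, 1e4)
    coords <- matrix(sample(0:40, 4), 2)
    P <- coords * 500
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    Q <- t(s * R %*% t(P)) + rep(t, each = 2)
    m <- calibrate(anchors(coords[, 1], coords[, 2], Q[, 1], Q[, 2]), 500)
    expect_equal(m$scale, s, tolerance = 1e-9)
    expect_equal(m$theta_deg %% 360, (th * 180 / pi) %% 360, tolerance = 1e-6)
    # grid_to_stage o stage_to_grid is the identity on lattice points
    cc <- c(sample(0:40, 1), sample(0:40, 1))
    pos <- grid_to_stage(m, cc)
    back <- stage_to_grid(m, pos)
    expect_identical(unname(back$coord), as.integer(cc))
    expect_lt(back$residual, 1e-6 * max(1, abs(s)))
  }
})

test_that("scale factor equals the stage/grid distance ratio", {
  a <- anchors(c(3, 7), c(2, 5), c(120.5, 980.2), c(-40, 310))
  m <- calibrate(a, 500)
  d_stage <- sqrt(diff(a$stage_x)^2 + diff(a$stage_y)^2)
  d_grid <- 500 * sqrt(diff(a$x_index)^2 + diff(a$y_index)^2)
  expect_equal(m$scale, d_stage / d_grid, tolerance = 1e-12)
})

test_that("stage_to_grid rounds to the nearest site with the documented tie-break", {
  m <- calibrate(anchors(c(0, 1), c(0, 0), c(0, 500), c(0, 0)), 500)
  r <- stage_to_grid(m, c(1500, 2000))
  expect_identical(unname(r$coord), c(3L, 4L))
  expect_equal(r$residual, 0)
  r2 <- stage_to_grid(m, c(1500 + 125, 2000))
  expect_identical(unname(r2$coord), c(3L, 4L))
  expect_equal(r2$residual, 125)
  r3 <- stage_to_grid(m, c(1750, 2000)) # midpoint: round toward lower index
  expect_identical(unname(r3$coord)[1], 3L)
})

test_that("affine calibration recovers anisotropic deformation exactly", {
  g <- expand.grid(x = 0:1, y = 0:1)
  a <- anchors(g$x, g$y, g$x * 500 * 1.10, g$y * 500 * 1.00)
  m <- calibrate(a, 500, model = "affine")
  expect_equal(m$sx, 1.10, tolerance = 1e-9)
  expect_equal(m$sy, 1.00, tolerance = 1e-9)
  expect_equal(m$shear_deg, 0, tolerance = 1e-9)
  rep <- deformation_report(m)
  expect_true(all(rep$residuals$residual < 1e-9))

  # pure rotation: unit scales, zero shear
  th <- 33 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Q <- t(R %*% t(cbind(g$x, g$y) * 500))
  m2 <- calibrate(anchors(g$x, g$y, Q[, 1], Q[, 2]), 500, model = "affine")
  expect_equal(c(m2$sx, m2$sy), c(1, 1), tolerance = 1e-9)
  expect_equal(m2$shear_deg, 0, tolerance = 1e-6)

  # a displaced anchor shows up in its own residual
  g3 <- expand.grid(x = 0:2, y = 0:2)
  sx3 <- g3$x * 500; sy3 <- g3$y * 500
  sx3[5] <- sx3[5] + 50
  m3 <- calibrate(anchors(g3$x, g3$y, sx3, sy3), 500, model = "affine")
  rep3 <- deformation_report(m3)
  expect_equal(which.max(rep3$residuals$residual), 5L)
  expect_gt(max(rep3$residuals$residual), 30)
})

test_that("noisy-anchor estimates tighten as sigma over sqrt(n)", {
  set.seed(9)
  sim_rmse <- function(n_anchor, sigma, reps = 200) {
    errs <- replicate(reps, {
      coords <- cbind(sample(0:30, n_anchor), sample(0:30, n_anchor))
      Q <- coords * 500 + matrix(rnorm(2 * n_anchor, 0, sigma), ncol = 2)
      m <- calibrate(anchors(coords[, 1], coords[, 2], Q[, 1], Q[, 2]), 500,
                     model = "affine")
      m$scale - 1
    })
    c(bias = mean(errs), rmse = sqrt(mean(errs^2)))
  }
  r4 <- sim_rmse(4, 10)
  r16 <- sim_rmse(16, 10)
  expect_lt(abs(r4["bias"]), r4["rmse"]) # no systematic bias
  # rmse should shrink roughly as 1/sqrt(n): allow generous slack
  expect_lt(r16["rmse"], r4["rmse"] / 1.3)
})

test_that("piecewise-affine mapping reproduces every anchor exactly", {
  set.seed(21)
  g <- expand.grid(x = 0:2, y = 0:2)
  a <- anchors(g$x, g$y,
               g$x * 500 * 1.05 + rnorm(9, 0, 8),
               g$y * 500 * 0.97 + rnorm(9, 0, 8))
  m <- calibrate(a, 500, model = "piecewise_affine")
  pred <- grid_to_stage(m, cbind(a$x_index, a$y_index))
  expect_lt(max(abs(pred - cbind(a$stage_x, a$stage_y))), 1e-9)
})

test_that("degenerate anchor sets raise the documented errors", {
  expect_error(calibrate(anchors(0, 0, 0, 0), 500), "at least 2")
  expect_error(calibrate(anchors(c(0, 0), c(0, 0), c(0, 1), c(0, 1)), 500),
               "distinct")
  col3 <- anchors(c(0, 1, 2), c(0, 0, 0), c(0, 500, 1000), c(0, 0, 0))
  expect_error(calibrate(col3, 500, model = "affine"), "collinear")
})

test_that("reflection is detected from the chiral decoded lattice", {
  det <- data.frame(x_index = c(0, 1, 0), y_index = c(0, 0, 1),
                    px_row = c(100, 100, 50), px_col = c(10, 60, 10),
                    orientation_deg = 0, confidence = 1)
  expect_false(detect_reflection(det)) # y up when row decreases: proper
  det_m <- det; det_m$px_row <- c(100, 100, 150) # mirrored view
  expect_true(detect_reflection(det_m))
})

test_that("mapping JSON serialisation carries the documented fields", {
  m <- calibrate(anchors(c(0, 1), c(0, 0), c(5, 505), c(7, 7)), 500)
  path <- withr::local_tempfile(fileext = ".json")
  write_mapping_json(m, path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(j$model, "similarity")
  expect_equal(j$scale, 1)
  expect_equal(c(j$tx, j$ty), c(5, 7))
})
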