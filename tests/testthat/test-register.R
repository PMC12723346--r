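# Fiducial correspondence, transform estimation, warping and overlay.

make_pairs <- function(n = 6, theta = 30, scale = 0.8, t = c(50, -20), seed = 1) {
  set.seed(seed)
  mov <- cbind(col = runif(n, 20, 400), row = runif(n, 20, 400))
  th <- theta * pi / 180
  fx <- scale * (cos(th) * mov[, 1] - sin(th) * mov[, 2]) + t[1]
  fy <- scale * (sin(th) * mov[, 1] + cos(th) * mov[, 2]) + t[2]
  data.frame(x_index = seq_len(n), y_index = 0,
             fixed_row = fy, fixed_col = fx,
             moving_row = mov[, 2], moving_col = mov[, 1])
}

test_that("codes shared between two detection sets are paired by identity", {
  f <- data.frame(x_index = c(0, 1, 2, 3, 9), y_index = 0,
                  px_row = 1:5, px_col = 1:5, orientation_deg = 0,
                  confidence = c(1, 1, 1, 1, 1))
  m <- data.frame(x_index = c(1, 2, 3, 0, 7), y_index = 0,
                  px_row = 11:15, px_col = 11:15, orientation_deg = 0,
                  confidence = 1)
  corr <- match_by_code(f, m)
  expect_equal(nrow(corr$pairs), 4L)
  expect_error(match_by_code(f, transform(m, x_index = x_index + 50)),
               "insufficient correspondences")
  # a duplicate coordinate keeps the higher-confidence detection
  f2 <- rbind(f, data.frame(x_index = 1, y_index = 0, px_row = 99, px_col = 99,
                            orientation_deg = 0, confidence = 0.5))
  corr2 <- match_by_code(f2, m)
  expect_equal(corr2$pairs$fixed_row[corr2$pairs$x_index == 1], 2)
  expect_true(any(grepl("duplicate", corr2$report)))
})

test_that("a known similarity is recovered to numerical precision", {
  pairs <- make_pairs()
  tr <- estimate_transform(pairs)
  expect_equal(tr$theta_deg, 30, tolerance = 1e-9)
  expect_equal(tr$scale, 0.8, tolerance = 1e-12)
  expect_lt(tr$rms_residual, 1e-10)
  # identity correspondences give the identity matrix
  idp <- make_pairs(theta = 0, scale = 1, t = c(0, 0))
  tid <- estimate_transform(idp)
  expect_equal(tid$matrix, cbind(diag(2), c(0, 0)), tolerance = 1e-12)
})

test_that("forward and reverse fits are mutually inverse", {
  pairs <- make_pairs(theta = 77, scale = 1.3, t = c(-12, 8))
  rev <- pairs
  rev[, c("fixed_row", "fixed_col", "moving_row", "moving_col")] <-
    pairs[, c("moving_row", "moving_col", "fixed_row", "fixed_col")]
  M1 <- rbind(estimate_transform(pairs)$matrix, c(0, 0, 1))
  M2 <- rbind(estimate_transform(rev)$matrix, c(0, 0, 1))
  expect_equal(M1 %*% M2, diag(3), tolerance = 1e-9)
})

test_that("noisy affine fit leaves the expected residual", {
  set.seed(4)
  reps <- 60
  sig <- 0.5
  n <- 10
  rms <- replicate(reps, {
    pairs <- make_pairs(n = n, theta = 15, scale = 1.1, seed = sample.int(1e6, 1))
    pairs$fixed_row <- pairs$fixed_row + rnorm(n, 0, sig)
    pairs$fixed_col <- pairs$fixed_col + rnorm(n, 0, sig)
    estimate_transform(pairs, "affine")$rms_residual
  })
  # per-pair distances combine two noisy components:
  # rms ~ sigma * sqrt(2 * (1 - dof/(2n))) with 6 dof over 2n = 20
  expect_equal(mean(rms), sig * sqrt(2 * (1 - 6 / (2 * n))), tolerance = 0.1)
})

test_that("alpha endpoints return the fixed and the warped image", {
  set.seed(2)
  fixed <- matrix(runif(80 * 60), 80, 60)
  moving <- matrix(runif(80 * 60), 80, 60)
  idt <- structure(list(model = "similarity", matrix = cbind(diag(2), c(0, 0)),
                        theta_deg = 0, scale = 1, rms_residual = 0),
                   class = "image_transform")
  expect_equal(warp_and_overlay(fixed, moving, idt, alpha = 0)$composite, fixed)
  ov1 <- warp_and_overlay(fixed, moving, idt, alpha = 1)
  inside <- !is.na(ov1$warped)
  expect_equal(ov1$composite[inside], moving[inside], tolerance = 1e-12)
  half <- warp_and_overlay(fixed, moving, idt, alpha = 0.5)$composite
  expect_equal(half[inside], ((fixed + moving) / 2)[inside], tolerance = 1e-12)
})

test_that("registration report flags a corrupted pair as the max residual", {
  pairs <- make_pairs()
  pairs$fixed_col[3] <- pairs$fixed_col[3] + 25
  tr <- estimate_transform(pairs)
  rep <- registration_report(pairs, tr, pixel_size = 0.5)
  expect_equal(which.max(rep$residuals$residual_px), 3L)
  expect_equal(rep$residuals$residual_um, rep$residuals$residual_px * 0.5)
  # exact fit: all residuals zero
  rep0 <- registration_report(make_pairs(), estimate_transform(make_pairs()))
  expect_lt(rep0$max_px, 1e-9)
})

test_that("two synthetic modalities of one layout co-register end to end", {
  sp <- small_binary_spec()
  lay <- generate_grid(sp, c(600, 600))
  cam_f <- camera_model(1, c(512, 512), rotation = 0, translation = c(235, 235),
                        polarity = "dark_features", blur_sigma = 1,
                        noise_sigma = 0.01, seed = 3)
  cam_m <- camera_model(1.2, c(512, 512), rotation = 15, translation = c(232, 238),
                        polarity = "bright_features", blur_sigma = 1,
                        noise_sigma = 0.01, seed = 4)
  img_f <- render(lay, cam_f)
  img_m <- render(lay, cam_m)
  det_f <- detect_codes(img_f, decode_hints(sp, 1))
  det_m <- detect_codes(img_m, decode_hints(sp, 1.2))
  corr <- match_by_code(det_f, det_m)
  expect_gte(nrow(corr$pairs), 3)
  tr <- estimate_transform(corr)
  rep <- registration_report(corr, tr)
  expect_lt(rep$rms_px, 0.5)
  # recovered rotation and scale match the camera ground truth: the moving
  # camera is rotated +15 deg, so mapping moving pixels onto fixed pixels
  # rotates by -15 deg; its coarser pixels (1.2 um) map to 1.2 fixed pixels
  expect_equal(tr$theta_deg, 345, tolerance = 0.2)
  expect_equal(tr$scale, 1.2, tolerance = 0.005)
  ov <- warp_and_overlay(img_f, img_m, tr, alpha = 0.5)
  inside <- !is.na(ov$warped)
  expect_gt(mean(inside), 0.5)
})
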