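# Machine-vision decoding against the renderer's ground truth.

test_that("a clean field decodes completely with sub-pixel positions", {
  sc <- render_field(rotation = 0, blur = 2, noise = 0) # blur = 0.2 f
  det <- detect_codes(sc$img, decode_hints(small_binary_spec(), 1))
  m <- merge(sc$gt, det, by = c("x_index", "y_index"))
  expect_equal(nrow(det), nrow(sc$gt))
  expect_equal(nrow(m), nrow(sc$gt))
  err <- sqrt((m$px_row.x - m$px_row.y)^2 + (m$px_col.x - m$px_col.y)^2)
  expect_lt(max(err), 1)
  expect_true(all(abs(det$orientation_deg %% 360) < 1 |
                  abs(det$orientation_deg %% 360 - 360) < 1))
})

test_that("the align mark disambiguates a 180-degree rotated field", {
  sc <- render_field(rotation = 180, blur = 2, noise = 0)
  det <- detect_codes(sc$img, decode_hints(small_binary_spec(), 1))
  m <- merge(sc$gt, det, by = c("x_index", "y_index"))
  expect_equal(nrow(m), nrow(sc$gt))
  expect_true(all(abs(det$orientation_deg - 180) < 1))
})

test_that("a blank image yields an empty detection table, not an error", {
  blank <- matrix(0.5, 256, 256)
  det <- detect_codes(blank, decode_hints(small_binary_spec(), 1))
  expect_s3_class(det, "data.frame")
  expect_equal(nrow(det), 0L)
})

test_that("polarity auto-detection handles brightfield and darkfield alike", {
  for (pol in c("bright_features", "dark_features")) {
    sc <- render_field(rotation = 25, blur = 1, noise = 0.02, polarity = pol)
    det <- detect_codes(sc$img, decode_hints(small_binary_spec(), 1))
    m <- merge(sc$gt, det, by = c("x_index", "y_index"))
    expect_gte(nrow(m), nrow(sc$gt) - 1)
    # nothing decoded wrongly (each coordinate matches the code there)
    expect_true(all_detections_truthful(det, sc$layout, sc$camera))
    expect_equal(attr(det, "polarity"), pol)
  }
})

test_that("a misleading pixel-size hint within 40 percent still decodes", {
  sc <- render_field(rotation = 10, blur = 1, noise = 0.01)
  for (hs in c(0.7, 1.4)) {
    det <- detect_codes(sc$img, decode_hints(small_binary_spec(), hs))
    m <- merge(sc$gt, det, by = c("x_index", "y_index"))
    expect_gte(nrow(m), nrow(sc$gt) - 1)
    expect_true(all_detections_truthful(det, sc$layout, sc$camera))
  }
})

test_that("ternary fields decode through the same pipeline", {
  sp <- grid_spec("ternary", 10, 200)
  lay <- generate_grid(sp, c(600, 600))
  cam <- camera_model(1, c(512, 512), rotation = 40, translation = c(235, 235),
                      blur_sigma = 1, noise_sigma = 0.01, seed = 6)
  img <- render(lay, cam)
  gt <- ground_truth(lay, cam)
  det <- detect_codes(img, decode_hints(sp, 1))
  m <- merge(gt, det, by = c("x_index", "y_index"))
  expect_gte(nrow(m), nrow(gt) - 1)
  expect_equal(nrow(det), nrow(m))
})

test_that("the consistency filter removes a corrupted detection", {
  sc <- render_field(rotation = 0, blur = 1, noise = 0)
  hints <- decode_hints(small_binary_spec(), 1)
  det <- detect_codes(sc$img, hints, consistency = FALSE)
  bad <- det[1, ]
  bad$x_index <- bad$x_index + 16L # single-bit corruption
  det_bad <- rbind(det[-1, ], bad)
  kept <- neighbor_consistency_filter(det_bad, hints)
  expect_equal(nrow(kept), nrow(det) - 1L)
  expect_false(paste(bad$x_index, bad$y_index) %in%
                 paste(kept$x_index, kept$y_index))
  # an all-consistent set passes unchanged (up to row order)
  kept2 <- neighbor_consistency_filter(det, hints)
  expect_equal(nrow(kept2), nrow(det))
  # of two geometrically inconsistent detections (their positions imply a
  # rotation their decoded orientations contradict) the lower-confidence
  # one is removed
  two <- det[1:2, ]
  d0 <- sqrt(diff(two$px_row)^2 + diff(two$px_col)^2)
  two$px_row[2] <- two$px_row[1] - d0 * sin(40 * pi / 180)
  two$px_col[2] <- two$px_col[1] + d0 * cos(40 * pi / 180)
  two$confidence <- c(0.99, 0.85)
  kept3 <- neighbor_consistency_filter(two, hints)
  expect_equal(nrow(kept3), 1L)
  expect_equal(kept3$confidence, 0.99)
})

test_that("rectified single-code crops decode in every scheme", {
  for (scheme in c("binary", "ternary", "decimal", "planet")) {
    sp <- grid_spec(scheme, 10, 2000)
    set.seed(8)
    cap <- axis_capacity(sp)
    for (k in 1:4) {
      coord <- sample(0:(cap - 1), 2, replace = TRUE)
      lay <- generate_grid(grid_spec(scheme, 10, 2000), c(1, 1))
      lay$placements <- data.frame(x_index = coord[1], y_index = coord[2],
                                   x_um = 0, y_um = 0)
      fp <- footprint(sp)
      cam <- camera_model(0.5, c(round(fp[2] / 0.5), round(fp[1] / 0.5)),
                          translation = fp / 2, blur_sigma = 0.5)
      crop <- render(lay, cam)
      got <- read_code_crop(crop, sp)
      expect_identical(unname(got), as.integer(coord),
                       info = paste(scheme, paste(coord, collapse = ",")))
    }
  }
})

test_that("detection CSV round-trips", {
  sc <- render_field(blur = 1)
  det <- detect_codes(sc$img, decode_hints(small_binary_spec(), 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_detections(det, path)
  det2 <- read_detections(path)
  expect_equal(det2$x_index, det$x_index)
  expect_equal(det2$px_row, det$px_row, tolerance = 1e-9)
})
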