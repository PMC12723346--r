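# Grid layout, spacing selection, densities, GDSII and preview export.

test_that("spacing selection reproduces the bottleneck-FOV rule", {
  # 600 um confocal field of view with the 80 um binary code -> 500 um
  expect_equal(select_spacing(600, 80), 500)
  expect_equal(select_spacing(600, grid_spec("binary", 80 / 7, 500)), 500)
  expect_equal(select_spacing(1300, 80), 1200)
  expect_error(select_spacing(80, 80), "too small")
  # maximality and feasibility against brute force over the quantum lattice
  for (fov in c(250, 333, 870, 1999)) {
    fp <- 70; q <- 100
    s <- select_spacing(fov, fp, q)
    expect_true(s + fp <= fov)            # >= 1 code in any window
    expect_true(s + q + fp > fov)         # maximal on the quantum lattice
    expect_equal(s %% q, 0)
  }
})

test_that("marker density matches the pitch arithmetic", {
  expect_equal(unname(marker_density(500)), c(4, 400))
  expect_equal(unname(marker_density(1000)[1]), 1)
  expect_equal(unname(marker_density(250)[1]), 16)
})

test_that("generate_grid populates exactly the sites whose codes fit", {
  sp <- grid_spec("binary", 10, 500)
  lay <- generate_grid(sp, c(1000, 1000))
  expect_equal(nrow(lay$placements), 4L)
  expect_setequal(paste(lay$placements$x_index, lay$placements$y_index),
                  c("0 0", "1 0", "0 1", "1 1"))
  expect_equal(lay$placements$x_um, lay$placements$x_index * 500)

  expect_equal(nrow(generate_grid(sp, c(60, 60))$placements), 0L)

  big <- generate_grid(sp, c(10000, 10000))
  expect_equal(nrow(big$placements), 400L) # matches 4 codes / mm^2 over 1 cm^2
  expect_false(anyDuplicated(big$placements[, 1:2]) > 0)

  tiny <- grid_spec("binary", 10, 500, symbols_per_axis = 2)
  expect_error(generate_grid(tiny, c(10000, 10000)), "addresses only")
})

test_that("GDSII files carry a 1 nm database unit and round-trip losslessly", {
  sp <- grid_spec("binary", 10, 500)
  lay <- generate_grid(sp, c(1000, 1000))
  path <- withr::local_tempfile(fileext = ".gds")
  write_gdsii(lay, path)
  gds <- read_gdsii(path)
  expect_equal(gds$db_unit_m, 1e-9)
  expect_equal(gds$user_unit_per_db, 1e-3)

  got <- gdsii_rectangles(gds)
  want <- do.call(rbind, lapply(seq_len(nrow(lay$placements)), function(k) {
    g <- encode(c(lay$placements$x_index[k], lay$placements$y_index[k]), sp)
    data.frame(x0 = round((g$rectangles$x0 + lay$placements$x_um[k]) * 1000),
               y0 = round((g$rectangles$y0 + lay$placements$y_um[k]) * 1000),
               x1 = round((g$rectangles$x1 + lay$placements$x_um[k]) * 1000),
               y1 = round((g$rectangles$y1 + lay$placements$y_um[k]) * 1000))
  }))
  ord <- function(d) d[order(d$x0, d$y0, d$x1, d$y1), ]
  expect_equal(ord(got), ord(want), ignore_attr = TRUE)
})

test_that("an empty layout still writes a valid GDSII with an empty top cell", {
  sp <- grid_spec("binary", 10, 500)
  lay <- generate_grid(sp, c(60, 60))
  path <- withr::local_tempfile(fileext = ".gds")
  write_gdsii(lay, path)
  gds <- read_gdsii(path)
  expect_true("MUGRID" %in% names(gds$cells))
  expect_equal(nrow(gdsii_rectangles(gds)), 0L)
})

test_that("SVG preview holds one group per code and spans the extent", {
  sp <- grid_spec("binary", 10, 500)
  lay <- generate_grid(sp, c(1000, 1000))
  path <- withr::local_tempfile(fileext = ".svg")
  write_preview(lay, path)
  doc <- xml2::read_xml(path)
  groups <- xml2::xml_find_all(doc, ".//*[local-name() = 'g']")
  expect_length(groups, 4L)
  vb <- strsplit(xml2::xml_attr(doc, "viewBox"), " ")[[1]]
  expect_equal(as.numeric(vb), c(0, 0, 1000, 1000))
})

test_that("layout JSON round-trips spec and placements", {
  sp <- grid_spec("ternary", 5, 300, fill_factor = 0.8)
  lay <- generate_grid(sp, c(900, 600))
  path <- withr::local_tempfile(fileext = ".json")
  write_layout_json(lay, path)
  lay2 <- read_layout_json(path)
  expect_equal(lay2$spec$scheme, "ternary")
  expect_equal(lay2$spec$fill_factor, 0.8)
  expect_equal(lay2$extent, c(900, 600))
  expect_equal(lay2$placements, lay$placements)
})
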