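# Symbol encoding and code geometry.

test_that("binary geometry follows the canonical L-layout", {
  sp <- grid_spec("binary", 10, 500)
  g0 <- encode(c(0, 0), sp)
  expect_equal(nrow(g0$rectangles), 1L) # align mark only
  expect_equal(unlist(g0$rectangles[1, ], use.names = FALSE), c(0, 0, 10, 10))
  expect_equal(g0$footprint, c(70, 70))

  # coord (5, 3): x bits 000101 (MSB adjacent to align), y bits 000011
  g <- encode(c(5, 3), sp)
  r <- g$rectangles
  x_cells <- sort((r$x0[r$y0 == 0 & r$x0 > 0]) / 10)
  y_cells <- sort((r$y0[r$x0 == 0 & r$y0 > 0]) / 10)
  expect_equal(x_cells, c(4, 6)) # bits 4 and 6 of 000101
  expect_equal(y_cells, c(5, 6)) # bits 5 and 6 of 000011
})

test_that("all rectangles stay inside the footprint and are disjoint", {
  for (scheme in c("binary", "ternary", "decimal", "planet")) {
    sp <- grid_spec(scheme, 10, 2000)
    set.seed(7)
    cap <- axis_capacity(sp)
    for (k in 1:5) {
      coord <- sample(0:(cap - 1), 2, replace = TRUE)
      g <- encode(coord, sp)
      r <- g$rectangles
      expect_true(all(r$x0 >= -1e-9 & r$y0 >= -1e-9 &
                      r$x1 <= g$footprint[1] + 1e-9 &
                      r$y1 <= g$footprint[2] + 1e-9),
                  info = paste(scheme, paste(coord, collapse = ",")))
      if (nrow(r) > 1) {
        for (i in 1:(nrow(r) - 1)) for (j in (i + 1):nrow(r)) {
          overlap <- max(0, min(r$x1[i], r$x1[j]) - max(r$x0[i], r$x0[j])) *
                     max(0, min(r$y1[i], r$y1[j]) - max(r$y0[i], r$y0[j]))
          expect_lt(overlap, 1e-9)
        }
      }
    }
  }
})

test_that("exhaustive binary and sampled ternary round-trips are the identity", {
  spb <- grid_spec("binary", 10, 500)
  g <- expand.grid(x = 0:63, y = 0:63)
  ok_b <- vapply(seq_len(nrow(g)), function(k) {
    s <- code_symbols(c(g$x[k], g$y[k]), spb)
    identical(unname(logical_decode(s$x, s$y, spb)), c(g$x[k], g$y[k]) * 1L)
  }, logical(1))
  expect_true(all(ok_b))
  expect_length(ok_b, 4096L)
  spt <- grid_spec("ternary", 10, 500)
  set.seed(11)
  xs <- sample(0:728, 1000, replace = TRUE)
  ys <- sample(0:728, 1000, replace = TRUE)
  ok_t <- vapply(seq_len(1000), function(k) {
    s <- code_symbols(c(xs[k], ys[k]), spt)
    identical(unname(logical_decode(s$x, s$y, spt)), c(xs[k], ys[k]) * 1L)
  }, logical(1))
  expect_true(all(ok_t))
})

test_that("decimal and planet symbol round-trips hold for every coordinate", {
  for (scheme in c("decimal", "planet")) {
    sp <- grid_spec(scheme, 10, 2000)
    ok <- vapply(0:99, function(x) {
      s <- axis_symbols(x, sp)
      unname(logical_decode(s, s, sp))[1] == x
    }, logical(1))
    expect_true(all(ok))
  }
})

test_that("ternary trit values map to empty, half-width and full cells", {
  sp <- grid_spec("ternary", 10, 500)
  g <- encode(c(logical_decode(c(0, 0, 0, 0, 1, 2), rep(0, 6), sp)[1], 0), sp)
  r <- g$rectangles
  widths <- sort(r$x1 - r$x0)
  expect_equal(widths, c(5, 10, 10)) # half-width trit-1, full trit-2, align
})

test_that("out-of-range coordinates and symbols raise informative errors", {
  sp <- grid_spec("binary", 10, 500)
  expect_error(encode(c(64, 0), sp), "x_index 64 out of range")
  expect_error(encode(c(0, -1), sp), "y_index")
  expect_error(logical_decode(rep(2, 6), rep(0, 6), sp), "invalid x symbol")
  expect_error(logical_decode(rep(0, 5), rep(0, 6), sp), "length")
})

test_that("footprints follow the layout rules and scale with feature size", {
  expect_equal(footprint(grid_spec("binary", 10, 500)), c(70, 70))
  expect_equal(footprint(grid_spec("binary", 0.4, 500)), c(2.8, 2.8))
  expect_equal(footprint(grid_spec("ternary", 10, 500)), c(70, 70))
  # scale equivariance of the full geometry
  sp1 <- grid_spec("binary", 10, 500)
  sp2 <- grid_spec("binary", 25, 1250)
  g1 <- encode(c(37, 22), sp1); g2 <- encode(c(37, 22), sp2)
  expect_equal(as.matrix(g2$rectangles), as.matrix(g1$rectangles) * 2.5)
})

test_that("chirality holds whenever both arms carry a set symbol", {
  # rotating the geometry by 90/180/270 degrees about the footprint centre
  # never reproduces a valid encoding of another coordinate when both arms
  # are non-empty (one-armed codes are genuinely rotation-ambiguous)
  sp <- grid_spec("binary", 10, 500)
  rot_rects <- function(r, fp, quarter_turns) {
    m <- as.matrix(r)
    for (q in seq_len(quarter_turns)) {
      # (x, y) -> (y, fp - x), applied to both corners then re-sorted
      m <- cbind(pmin(m[, 2], m[, 4]), pmin(fp - m[, 3], fp - m[, 1]),
                 pmax(m[, 2], m[, 4]), pmax(fp - m[, 3], fp - m[, 1]))
    }
    m[order(m[, 1], m[, 2]), , drop = FALSE]
  }
  canon <- function(m) paste(round(as.vector(t(m)), 6), collapse = ";")
  set.seed(3)
  for (k in 1:25) {
    coord <- sample(1:63, 2) # both arms non-zero
    g <- encode(coord, sp)
    base <- canon(rot_rects(g$rectangles, 70, 0))
    for (q in 1:3)
      expect_false(canon(rot_rects(g$rectangles, 70, q)) == base)
  }
})
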