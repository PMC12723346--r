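# Symbol-level encoding and the physical geometry of single code symbols.
#
# All geometry is expressed in the code-local frame: micrometres, origin at
# the align-mark corner, x to the right, y up. Rectangles are axis-aligned
# (x0, y0, x1, y1) with x0 < x1, y0 < y1 and pairwise-disjoint interiors.

#' Convert an axis index to its symbol vector
#'
#' Expands a non-negative integer in the scheme's base, most significant
#' symbol first, zero-padded to `symbols_per_axis`.
#'
#' @param value non-negative integer below [axis_capacity()].
#' @param spec a [grid_spec()].
#' @return integer vector of length `spec$symbols_per_axis`, MSB first.
#' @export
axis_symbols <- function(value, spec) {
  base <- scheme_base(spec$scheme)
  n <- spec$symbols_per_axis
  if (value < 0 || value >= base^n)
    stop(sprintf("value %d out of range for %d base-%d symbols", value, n, base))
  out <- integer(n)
  v <- as.integer(value)
  for (k in n:1) {
    out[k] <- v %% base
    v <- v %/% base
  }
  out
}

#' Symbol vectors of a grid coordinate
#'
#' The logical content of one code: the x-axis and y-axis symbol vectors
#' (bits, trits or digits), most significant symbol first. By convention the
#' most significant symbol sits in the lattice cell adjacent to the align
#' mark, so significance decreases with distance from it.
#'
#' @param coord length-2 vector `c(x_index, y_index)`.
#' @param spec a [grid_spec()].
#' @return list with integer vectors `x` and `y`.
#' @export
code_symbols <- function(coord, spec) {
  check_coordinate(coord[1], coord[2], spec)
  list(x = axis_symbols(coord[1], spec), y = axis_symbols(coord[2], spec))
}

#' Decode symbol vectors back to a grid coordinate
#'
#' Inverse of [code_symbols()]: evaluates the base expansion of each axis
#' vector (most significant symbol first).
#'
#' @param x_symbols,y_symbols integer symbol vectors of length
#'   `spec$symbols_per_axis`, values in `0..(base-1)`.
#' @param spec a [grid_spec()].
#' @return integer vector `c(x_index, y_index)`.
#' @export
logical_decode <- function(x_symbols, y_symbols, spec) {
  base <- scheme_base(spec$scheme)
  n <- spec$symbols_per_axis
  for (nm in c("x", "y")) {
    s <- if (nm == "x") x_symbols else y_symbols
    if (length(s) != n)
      stop(sprintf("%s symbol vector has length %d, expected %d", nm, length(s), n))
    if (any(is.na(s)) || any(s != round(s)) || any(s < 0) || any(s >= base))
      stop(sprintf("invalid %s symbol value for base-%d scheme", nm, base))
  }
  val <- function(s) as.integer(sum(s * base^((n - 1):0)))
  c(x_index = val(x_symbols), y_index = val(y_symbols))
}

# centred square/rectangle inside lattice cell (i, j), cell size f
.cell_rect <- function(i, j, f, w_frac, h_frac) {
  cx <- (i + 0.5) * f
  cy <- (j + 0.5) * f
  c(cx - w_frac * f / 2, cy - h_frac * f / 2,
    cx + w_frac * f / 2, cy + h_frac * f / 2)
}

# Two-of-five postal bar table: tall-bar positions per digit, weights
# 7-4-2-1-0 over the five bars, digit 0 encoded by weight 11 (7 + 4).
.planet_tall <- rbind(
  c(1,1,0,0,0), c(0,0,0,1,1), c(0,0,1,0,1), c(0,0,1,1,0), c(0,1,0,0,1),
  c(0,1,0,1,0), c(0,1,1,0,0), c(1,0,0,0,1), c(1,0,0,1,0), c(1,0,1,0,0))

# Seven-segment digits on a 3 x 5 subcell grid (columns x rows, row 0 at
# the bottom). Returns a logical 3 x 5 matrix of filled subcells.
.sevenseg_cells <- function(digit) {
  seg <- list( # a=top, b=top-right, c=bottom-right, d=bottom, e=bottom-left,
               # f=top-left, g=middle
    "0" = c("a","b","c","d","e","f"), "1" = c("b","c"),
    "2" = c("a","b","g","e","d"),     "3" = c("a","b","g","c","d"),
    "4" = c("f","g","b","c"),         "5" = c("a","f","g","c","d"),
    "6" = c("a","f","g","e","c","d"), "7" = c("a","b","c"),
    "8" = c("a","b","c","d","e","f","g"), "9" = c("a","b","f","g","c","d"))
  m <- matrix(FALSE, nrow = 3, ncol = 5) # [col, row]
  for (s in seg[[as.character(digit)]]) {
    switch(s,
      a = { m[, 5] <- TRUE },
      d = { m[, 1] <- TRUE },
      g = { m[, 3] <- TRUE },
      b = { m[3, 4:5] <- TRUE },
      c = { m[3, 1:2] <- TRUE },
      f = { m[1, 3:5] <- TRUE },
      e = { m[1, 1:3] <- TRUE })
  }
  m
}

# merge filled subcells into disjoint row-run rectangles
.cells_to_rects <- function(m, f, x_off, y_off) {
  rects <- list()
  for (row in seq_len(ncol(m))) {
    filled <- which(m[, row])
    if (!length(filled)) next
    runs <- split(filled, cumsum(c(1, diff(filled) != 1)))
    for (r in runs) {
      rects[[length(rects) + 1L]] <- c(
        x_off + (min(r) - 1) * f, y_off + (row - 1) * f,
        x_off + max(r) * f,       y_off + row * f)
    }
  }
  rects
}

#' Encode a grid coordinate into code geometry
#'
#' Produces the set of axis-aligned rectangles (code-local micrometre frame,
#' origin at the align-mark corner) realising one code symbol under the
#' spec's coding scheme.
#'
#' \strong{Binary}: a (n+1) x (n+1) cell lattice of cell size \eqn{f}; cell
#' (0,0) is the always-filled align mark, cells (1..n, 0) carry the x bits
#' and (0, 1..n) the y bits, most significant bit adjacent to the align
#' mark. A set bit is a square of side `fill_factor * f` centred in its
#' cell. \strong{Ternary}: same lattice; trit 0 leaves the cell empty, trit
#' 1 draws a half-width (f/2) rectangle, trit 2 the full square -- stroke
#' thickness is the third symbol level. \strong{Decimal}: rectilinear
#' seven-segment digits (stroke f, glyph 3f x 5f), the x-digit row above the
#' y-digit row, with a full-height align bar on the left. \strong{Planet}:
#' one bottom-aligned bar row (bar width f, gap f): a full-height frame bar,
#' the x digits then the y digits as five bars per digit (two tall of 5f,
#' three short of 2f, postal two-of-five weighting), and a closing frame
#' bar; the frame bars act as align marks and measurement points.
#'
#' @param coord length-2 vector `c(x_index, y_index)`, each within
#'   [axis_capacity()].
#' @param spec a [grid_spec()].
#' @return a `code_geometry`: list with `rectangles` (data.frame `x0, y0,
#'   x1, y1` in micrometres), `footprint` `c(width, height)`, `scheme`, and
#'   `coord`.
#' @export
#' @examples
#' sp <- grid_spec("binary", 10, 500)
#' g <- encode(c(5, 3), sp)
#' nrow(g$rectangles)  # align mark + set bits of 000101 and 000011
encode <- function(coord, spec) {
  syms <- code_symbols(coord, spec)
  f <- spec$feature_size
  ff <- spec$fill_factor
  n <- spec$symbols_per_axis
  rects <- list()
  add <- function(r) rects[[length(rects) + 1L]] <<- r

  if (spec$scheme %in% c("binary", "ternary")) {
    add(.cell_rect(0, 0, f, ff, ff)) # align mark
    for (k in seq_len(n)) {          # cell k holds symbol k (MSB at k = 1)
      sx <- syms$x[k]; sy <- syms$y[k]
      if (spec$scheme == "binary") {
        if (sx == 1) add(.cell_rect(k, 0, f, ff, ff))
        if (sy == 1) add(.cell_rect(0, k, f, ff, ff))
      } else {
        if (sx > 0) add(.cell_rect(k, 0, f, if (sx == 1) ff / 2 else ff, ff))
        if (sy > 0) add(.cell_rect(0, k, f, ff, if (sy == 1) ff / 2 else ff))
      }
    }
  } else if (spec$scheme == "decimal") {
    add(c(0, 0, f, 11 * f)) # full-height align bar, left edge
    for (k in seq_len(n)) { # glyphs MSD first, x row on top
      x_off <- (2 + 4 * (k - 1)) * f
      rects <- c(rects, .cells_to_rects(.sevenseg_cells(syms$x[k]), f, x_off, 6 * f))
      rects <- c(rects, .cells_to_rects(.sevenseg_cells(syms$y[k]), f, x_off, 0))
    }
  } else { # planet
    digits <- c(syms$x, syms$y)
    nbar <- 2L + 5L * length(digits)
    bar <- function(b, tall) c(2 * b * f, 0, (2 * b + 1) * f, if (tall) 5 * f else 2 * f)
    add(bar(0, TRUE))
    for (d in seq_along(digits)) {
      tall <- .planet_tall[digits[d] + 1L, ]
      for (p in 1:5) add(bar(1L + 5L * (d - 1L) + (p - 1L), tall[p] == 1))
    }
    add(bar(nbar - 1L, TRUE))
  }

  m <- do.call(rbind, rects)
  structure(
    list(rectangles = data.frame(x0 = m[, 1], y0 = m[, 2], x1 = m[, 3], y1 = m[, 4]),
         footprint = footprint(spec), scheme = spec$scheme,
         coord = c(x_index = as.integer(coord[1]), y_index = as.integer(coord[2]))),
    class = "code_geometry")
}

#' @export
print.code_geometry <- function(x, ...) {
  cat(sprintf("code_geometry: %s code (%d, %d), %d rectangles, footprint %g x %g um\n",
              x$scheme, x$coord[1], x$coord[2], nrow(x$rectangles),
              x$footprint[1], x$footprint[2]))
  invisible(x)
}
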