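# Placement of codes on a regular grid and layout serialization.

#' Select the inter-marker spacing from the bottleneck field of view
#'
#' The grid is designed so that at least one complete code falls inside the
#' field of view of the most constrained ("bottleneck") instrument. For an
#' axis-aligned square window of side `fov` this holds whenever
#' `spacing + footprint <= fov`; the rule returns the largest spacing on the
#' quantization grid satisfying it (round pitches are preferred on masks).
#'
#' @param fov side of the bottleneck field of view, micrometres.
#' @param spec a [grid_spec()], or directly a numeric code footprint in
#'   micrometres (length 1 or 2).
#' @param quantum spacing quantization step in micrometres (default 100).
#' @return spacing in micrometres.
#' @export
#' @examples
#' select_spacing(600, 80)   # 500, guaranteeing >= 1 code per 600 um window
select_spacing <- function(fov, spec, quantum = 100) {
  fp <- if (inherits(spec, "grid_spec")) max(footprint(spec)) else max(spec)
  if (!is.numeric(fov) || fov <= 0) stop("'fov' must be positive")
  s <- quantum * floor((fov - fp) / quantum)
  if (s < quantum)
    stop(sprintf(
      "field of view (%g um) too small: needs > footprint (%g um) + quantum (%g um)",
      fov, fp, quantum))
  s
}

#' Marker density for a given spacing
#'
#' @param spacing inter-marker pitch in micrometres.
#' @return named numeric `c(per_mm2, per_cm2)`; e.g. a 500 um pitch yields
#'   4 codes per mm^2.
#' @export
marker_density <- function(spacing) {
  if (!is.numeric(spacing) || spacing <= 0) stop("'spacing' must be positive")
  per_mm2 <- (1000 / spacing)^2
  c(per_mm2 = per_mm2, per_cm2 = per_mm2 * 100)
}

#' Generate a grid layout over a rectangular extent
#'
#' Populates every lattice site `(i, j)` whose code fits fully inside the
#' extent with the code for coordinate `(i, j)`. The anchor of each code
#' (its align-mark corner, the local origin) sits at physical
#' `(i * spacing, j * spacing)`; x indices increase with physical +x, y
#' indices with +y.
#'
#' @param spec a [grid_spec()].
#' @param extent length-2 numeric `c(width, height)` in micrometres.
#' @return a `grid_layout`: list with `spec`, `extent` and `placements`
#'   (data.frame `x_index, y_index, x_um, y_um`).
#' @export
generate_grid <- function(spec, extent) {
  if (length(extent) != 2L || any(extent <= 0)) stop("'extent' must be c(width, height) > 0")
  fp <- footprint(spec)
  s <- spec$spacing
  nx <- max(0L, as.integer(floor((extent[1] - fp[1]) / s)) + 1L)
  ny <- max(0L, as.integer(floor((extent[2] - fp[2]) / s)) + 1L)
  if (extent[1] < fp[1] || extent[2] < fp[2]) { nx <- 0L; ny <- 0L }
  cap <- axis_capacity(spec)
  if (nx > cap || ny > cap)
    stop(sprintf(
      "extent needs %d x %d sites but the %s scheme addresses only %d per axis; increase symbols_per_axis",
      nx, ny, spec$scheme, cap))
  if (nx == 0L || ny == 0L) {
    placements <- data.frame(x_index = integer(0), y_index = integer(0),
                             x_um = numeric(0), y_um = numeric(0))
  } else {
    g <- expand.grid(x_index = 0:(nx - 1L), y_index = 0:(ny - 1L))
    placements <- data.frame(x_index = g$x_index, y_index = g$y_index,
                             x_um = g$x_index * s, y_um = g$y_index * s)
  }
  structure(list(spec = spec, extent = as.numeric(extent), placements = placements),
            class = "grid_layout")
}

#' @export
print.grid_layout <- function(x, ...) {
  cat(sprintf("grid_layout: %d codes (%s, f = %g um) on %g um pitch over %g x %g um\n",
              nrow(x$placements), x$spec$scheme, x$spec$feature_size,
              x$spec$spacing, x$extent[1], x$extent[2]))
  invisible(x)
}

#' Write an SVG preview of a layout
#'
#' Vector preview for documentation: one `<g>` group per code, one `<rect>`
#' per geometry rectangle, in micrometre user units. SVG y runs downward, so
#' physical y is flipped about the extent height.
#'
#' @param layout a [generate_grid()] layout.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_preview <- function(layout, path) {
  W <- layout$extent[1]; H <- layout$extent[2]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" viewBox="0 0 %g %g" width="%gmm" height="%gmm">',
    W, H, W / 1000 * 10, H / 1000 * 10), con)
  writeLines(sprintf('<rect x="0" y="0" width="%g" height="%g" fill="white"/>', W, H), con)
  pl <- layout$placements
  for (k in seq_len(nrow(pl))) {
    geom <- encode(c(pl$x_index[k], pl$y_index[k]), layout$spec)
    writeLines(sprintf('<g id="code_%d_%d">', pl$x_index[k], pl$y_index[k]), con)
    r <- geom$rectangles
    writeLines(sprintf(
      '<rect x="%g" y="%g" width="%g" height="%g" fill="black"/>',
      pl$x_um[k] + r$x0, H - (pl$y_um[k] + r$y1), r$x1 - r$x0, r$y1 - r$y0), con)
    writeLines('</g>', con)
  }
  writeLines('</svg>', con)
  invisible(path)
}

#' Serialize a layout to JSON
#' @param layout a `grid_layout`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_layout_json <- function(layout, path) {
  jsonlite::write_json(
    list(spec = unclass(layout$spec), extent = layout$extent,
         placements = layout$placements),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a layout from JSON
#' @param path file written by [write_layout_json()].
#' @return a `grid_layout`.
#' @export
read_layout_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- grid_spec(j$spec$scheme, j$spec$feature_size, j$spec$spacing,
                    j$spec$symbols_per_axis, j$spec$fill_factor)
  pl <- as.data.frame(j$placements)
  if (!nrow(pl)) pl <- data.frame(x_index = integer(0), y_index = integer(0),
                                  x_um = numeric(0), y_um = numeric(0))
  structure(list(spec = spec, extent = as.numeric(j$extent), placements = pl),
            class = "grid_layout")
}
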