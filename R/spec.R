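#' Grid specification for a coordinate-encoding fiducial microgrid
#'
#' A `grid_spec` bundles the coding scheme and the physical design
#' parameters that govern every geometry the package produces: the minimum
#' feature size \eqn{f} (the side of one bit square, the smallest fabricated
#' dimension), the inter-marker spacing (pitch between adjacent codes), and
#' the number of symbols encoded per axis.
#'
#' Addressable range per axis is `base^symbols_per_axis`: 64 for the default
#' 6-bit binary, 729 for 6-trit ternary, 100 for 2-digit decimal and postal
#' (PLANET) codes.
#'
#' @param scheme one of `"binary"`, `"ternary"`, `"decimal"`, `"planet"`.
#' @param feature_size minimum feature size \eqn{f} in micrometres; the side
#'   of a single bit square. Must be positive.
#' @param spacing inter-marker pitch in micrometres. Must exceed the code
#'   footprint so codes cannot overlap.
#' @param symbols_per_axis bits/trits/digits per axis. Defaults to 6 for
#'   binary and ternary, 2 for decimal and planet.
#' @param fill_factor fraction in (0, 1]; a drawn bit square has side
#'   `fill_factor * feature_size`, centred in its lattice cell. Default 1.
#'
#' @return an object of class `grid_spec`.
#' @export
#' @examples
#' sp <- grid_spec("binary", feature_size = 10, spacing = 500)
#' footprint(sp)       # c(70, 70): seven times the minimum feature size
#' axis_capacity(sp)   # 64
grid_spec <- function(scheme = c("binary", "ternary", "decimal", "planet"),
                      feature_size, spacing,
                      symbols_per_axis = NULL, fill_factor = 1) {
  scheme <- match.arg(scheme)
  if (!is.numeric(feature_size) || length(feature_size) != 1L || feature_size <= 0)
    stop("'feature_size' must be a single positive number (micrometres)")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("'spacing' must be a single positive number (micrometres)")
  if (is.null(symbols_per_axis))
    symbols_per_axis <- if (scheme %in% c("binary", "ternary")) 6L else 2L
  symbols_per_axis <- as.integer(symbols_per_axis)
  if (symbols_per_axis < 1L) stop("'symbols_per_axis' must be a positive integer")
  if (!is.numeric(fill_factor) || fill_factor <= 0 || fill_factor > 1)
    stop("'fill_factor' must be in (0, 1]")
  sp <- structure(
    list(scheme = scheme, feature_size = feature_size, spacing = spacing,
         symbols_per_axis = symbols_per_axis, fill_factor = fill_factor),
    class = "grid_spec")
  fp <- footprint(sp)
  if (spacing <= max(fp))
    stop(sprintf("spacing (%g um) must exceed the code footprint (%g x %g um)",
                 spacing, fp[1], fp[2]))
  sp
}

#' @export
print.grid_spec <- function(x, ...) {
  fp <- footprint(x)
  cat(sprintf(
    "grid_spec: %s, f = %g um, spacing = %g um, %d symbols/axis (range %d), fill %g\n",
    x$scheme, x$feature_size, x$spacing, x$symbols_per_axis,
    axis_capacity(x), x$fill_factor))
  cat(sprintf("  footprint: %g x %g um\n", fp[1], fp[2]))
  invisible(x)
}

#' Numeric base of a coding scheme
#' @param scheme scheme name.
#' @return integer base (2, 3 or 10).
#' @export
scheme_base <- function(scheme) {
  switch(scheme, binary = 2L, ternary = 3L, decimal = 10L, planet = 10L,
         stop("unknown scheme: ", scheme))
}

#' Addressable coordinates per axis
#'
#' `base^symbols_per_axis`: the number of distinct index values one axis of
#' the grid can encode.
#' @param spec a [grid_spec()].
#' @return integer capacity per axis.
#' @export
axis_capacity <- function(spec) {
  as.integer(scheme_base(spec$scheme)^spec$symbols_per_axis)
}

#' Physical footprint of one code
#'
#' Side lengths of the bounding box of a single code symbol. For the binary
#' and ternary L-layouts on an (n+1) x (n+1) cell lattice this is
#' `(n+1) * f` per side -- seven times the minimum feature size for the
#' default 6-bit design (6 bits + 1 align mark). Decimal and planet
#' footprints follow their glyph/bar layout rules.
#'
#' @param spec a [grid_spec()].
#' @return numeric length-2 vector `c(width, height)` in micrometres.
#' @export
footprint <- function(spec) {
  f <- spec$feature_size
  n <- spec$symbols_per_axis
  switch(spec$scheme,
    binary  = c((n + 1) * f, (n + 1) * f),
    ternary = c((n + 1) * f, (n + 1) * f),
    # align bar (1f) + gap (1f) + n glyphs of 3f with 1f gaps; two glyph
    # rows of 5f with a 1f gap between them
    decimal = c((4 * n + 1) * f, 11 * f),
    # one bar row: frame + n x-digits + n y-digits + frame, 5 bars per
    # digit, bar width f, gap f => (2 + 10n) bars at 2f pitch
    planet  = c((2 * (2 + 10 * n) - 1) * f, 5 * f)
  )
}

#' Validate a grid coordinate against a spec
#' @param x_index,y_index non-negative integer grid indices.
#' @param spec a [grid_spec()].
#' @return invisibly, the coordinate as an integer vector.
#' @export
check_coordinate <- function(x_index, y_index, spec) {
  cap <- axis_capacity(spec)
  for (ax in c("x", "y")) {
    v <- if (ax == "x") x_index else y_index
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != round(v) || v < 0)
      stop(sprintf("%s_index must be a single non-negative integer", ax))
    if (v >= cap)
      stop(sprintf(
        "%s_index %d out of range: the %s scheme with %d symbols/axis addresses 0..%d",
        ax, as.integer(v), spec$scheme, spec$symbols_per_axis, cap - 1L))
  }
  invisible(c(x_index = as.integer(x_index), y_index = as.integer(y_index)))
}
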