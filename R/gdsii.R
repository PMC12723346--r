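# Minimal GDSII stream writer/reader for rectangle mask layouts.
#
# GDSII is a big-endian binary record format: each record is a 2-byte
# length, 1-byte record type, 1-byte data type, then payload. Reals use the
# excess-64 base-16 floating format. Only the records needed for flat
# rectangle masks are implemented: HEADER, BGNLIB, LIBNAME, UNITS, BGNSTR,
# STRNAME, BOUNDARY, LAYER, DATATYPE, XY, ENDEL, SREF, SNAME, ENDSTR,
# ENDLIB.

.GDS <- list(HEADER = 0x00, BGNLIB = 0x01, LIBNAME = 0x02, UNITS = 0x03,
             ENDLIB = 0x04, BGNSTR = 0x05, STRNAME = 0x06, ENDSTR = 0x07,
             BOUNDARY = 0x08, SREF = 0x0A, LAYER = 0x0D, DATATYPE = 0x0E,
             XY = 0x10, ENDEL = 0x11, SNAME = 0x12)

# excess-64 8-byte real: sign bit, 7-bit exponent (base 16, bias 64),
# 56-bit mantissa in [1/16, 1)
.gds_real8 <- function(v) {
  if (v == 0) return(as.raw(rep(0, 8)))
  sign <- 0L
  if (v < 0) { sign <- 0x80L; v <- -v }
  e <- 0L
  while (v >= 1) { v <- v / 16; e <- e + 1L }
  while (v < 1 / 16) { v <- v * 16; e <- e - 1L }
  bytes <- integer(7)
  for (i in 1:7) { v <- v * 256; b <- floor(v); bytes[i] <- b; v <- v - b }
  as.raw(c(bitwOr(sign, e + 64L), bytes))
}

.gds_parse_real8 <- function(bytes) {
  b1 <- as.integer(bytes[1])
  sign <- if (bitwAnd(b1, 0x80L) != 0L) -1 else 1
  e <- bitwAnd(b1, 0x7FL) - 64L
  mant <- sum(as.integer(bytes[2:8]) / 256^(1:7))
  sign * mant * 16^e
}

.gds_record <- function(rectype, datatype, payload = raw(0)) {
  len <- 4L + length(payload)
  c(writeBin(as.integer(len), raw(), size = 2, endian = "big"),
    as.raw(rectype), as.raw(datatype), payload)
}

.gds_int2 <- function(v) writeBin(as.integer(v), raw(), size = 2, endian = "big")
.gds_int4 <- function(v) writeBin(as.integer(v), raw(), size = 4, endian = "big")
.gds_str <- function(s) {
  b <- charToRaw(s)
  if (length(b) %% 2 == 1) b <- c(b, as.raw(0))
  b
}

.gds_cell_name <- function(xi, yi) sprintf("C_%d_%d", xi, yi)

#' Write a grid layout as a GDSII photomask file
#'
#' Emits a GDSII stream with a 1 nm database unit and 1 um user unit (UNITS
#' record 1e-3 / 1e-9). Each unique code becomes one structure holding its
#' rectangles as BOUNDARY elements; a top structure (default name
#' `"MUGRID"`) places them by structure reference at the code anchors.
#' Coordinates are rounded to the nearest nanometre.
#'
#' @param layout a [generate_grid()] layout.
#' @param path output file.
#' @param layer,datatype GDSII layer and datatype for all boundaries
#'   (defaults 1 and 0).
#' @param top_name name of the top structure.
#' @return invisibly, `path`.
#' @export
write_gdsii <- function(layout, path, layer = 1L, datatype = 0L,
                        top_name = "MUGRID") {
  ts <- rep(0L, 12) # modification + access timestamps, unused
  out <- c(
    .gds_record(.GDS$HEADER, 0x02, .gds_int2(600L)),
    .gds_record(.GDS$BGNLIB, 0x02, .gds_int2(ts)),
    .gds_record(.GDS$LIBNAME, 0x06, .gds_str("GRIDCODES")),
    .gds_record(.GDS$UNITS, 0x05, c(.gds_real8(1e-3), .gds_real8(1e-9))))
  pl <- layout$placements
  for (k in seq_len(nrow(pl))) {
    geom <- encode(c(pl$x_index[k], pl$y_index[k]), layout$spec)
    out <- c(out,
      .gds_record(.GDS$BGNSTR, 0x02, .gds_int2(ts)),
      .gds_record(.GDS$STRNAME, 0x06,
                  .gds_str(.gds_cell_name(pl$x_index[k], pl$y_index[k]))))
    r <- geom$rectangles
    for (i in seq_len(nrow(r))) {
      x0 <- round(r$x0[i] * 1000); y0 <- round(r$y0[i] * 1000)
      x1 <- round(r$x1[i] * 1000); y1 <- round(r$y1[i] * 1000)
      out <- c(out,
        .gds_record(.GDS$BOUNDARY, 0x00),
        .gds_record(.GDS$LAYER, 0x02, .gds_int2(layer)),
        .gds_record(.GDS$DATATYPE, 0x02, .gds_int2(datatype)),
        .gds_record(.GDS$XY, 0x03,
                    .gds_int4(c(x0, y0, x1, y0, x1, y1, x0, y1, x0, y0))),
        .gds_record(.GDS$ENDEL, 0x00))
    }
    out <- c(out, .gds_record(.GDS$ENDSTR, 0x00))
  }
  out <- c(out,
    .gds_record(.GDS$BGNSTR, 0x02, .gds_int2(ts)),
    .gds_record(.GDS$STRNAME, 0x06, .gds_str(top_name)))
  for (k in seq_len(nrow(pl))) {
    out <- c(out,
      .gds_record(.GDS$SREF, 0x00),
      .gds_record(.GDS$SNAME, 0x06,
                  .gds_str(.gds_cell_name(pl$x_index[k], pl$y_index[k]))),
      .gds_record(.GDS$XY, 0x03,
                  .gds_int4(round(c(pl$x_um[k], pl$y_um[k]) * 1000))),
      .gds_record(.GDS$ENDEL, 0x00))
  }
  out <- c(out,
    .gds_record(.GDS$ENDSTR, 0x00),
    .gds_record(.GDS$ENDLIB, 0x00))
  writeBin(out, path)
  invisible(path)
}

#' Read a GDSII stream file
#'
#' Parses the records written by [write_gdsii()] (and any flat GDSII using
#' BOUNDARY and SREF elements without magnification or rotation).
#'
#' @param path GDSII file.
#' @return list with `user_unit_per_db` (user units per database unit),
#'   `db_unit_m` (database unit in metres), and `cells`: a named list, each
#'   with `polygons` (list of n x 2 matrices in database units), `layers`,
#'   and `srefs` (data.frame `name, x, y` in database units).
#' @export
read_gdsii <- function(path) {
  raw <- readBin(path, raw(), n = file.size(path))
  pos <- 1L
  u16 <- function(i) as.integer(raw[i]) * 256L + as.integer(raw[i + 1L])
  i32 <- function(i) {
    v <- readBin(raw[i:(i + 3L)], integer(), size = 4, endian = "big")
    v
  }
  cells <- list()
  user_unit_per_db <- NA_real_; db_unit_m <- NA_real_
  cur <- NULL; cur_name <- NULL
  el <- NULL # pending element: list(kind, layer, xy)
  while (pos + 3L <= length(raw) + 1L) {
    len <- u16(pos)
    if (len < 4L) break
    rectype <- as.integer(raw[pos + 2L])
    payload <- if (len > 4L) raw[(pos + 4L):(pos + len - 1L)] else raw(0)
    if (rectype == .GDS$UNITS) {
      user_unit_per_db <- .gds_parse_real8(payload[1:8])
      db_unit_m <- .gds_parse_real8(payload[9:16])
    } else if (rectype == .GDS$BGNSTR) {
      cur <- list(polygons = list(), layers = integer(0),
                  srefs = data.frame(name = character(0), x = numeric(0), y = numeric(0)))
    } else if (rectype == .GDS$STRNAME || rectype == .GDS$SNAME) {
      nm <- rawToChar(payload[payload != as.raw(0)])
      if (rectype == .GDS$STRNAME) cur_name <- nm else el$name <- nm
    } else if (rectype == .GDS$ENDSTR) {
      cells[[cur_name]] <- cur; cur <- NULL; cur_name <- NULL
    } else if (rectype == .GDS$BOUNDARY) {
      el <- list(kind = "boundary", layer = NA_integer_)
    } else if (rectype == .GDS$SREF) {
      el <- list(kind = "sref", name = NA_character_)
    } else if (rectype == .GDS$LAYER) {
      el$layer <- u16(pos + 4L)
    } else if (rectype == .GDS$XY) {
      n <- (len - 4L) %/% 4L
      v <- vapply(seq_len(n), function(k) i32(pos + 4L + 4L * (k - 1L)), numeric(1))
      el$xy <- matrix(v, ncol = 2, byrow = TRUE)
    } else if (rectype == .GDS$ENDEL) {
      if (identical(el$kind, "boundary")) {
        cur$polygons[[length(cur$polygons) + 1L]] <- el$xy
        cur$layers <- c(cur$layers, el$layer)
      } else if (identical(el$kind, "sref")) {
        cur$srefs <- rbind(cur$srefs,
                           data.frame(name = el$name, x = el$xy[1, 1], y = el$xy[1, 2]))
      }
      el <- NULL
    }
    pos <- pos + len
  }
  list(user_unit_per_db = user_unit_per_db, db_unit_m = db_unit_m, cells = cells)
}

#' Flatten a parsed GDSII library to rectangles
#'
#' Resolves one level of structure references from a top structure and
#' returns the bounding boxes of all boundary polygons in database units
#' (nanometres for files written by [write_gdsii()]).
#'
#' @param gds result of [read_gdsii()].
#' @param top_name top structure name (default `"MUGRID"`).
#' @return data.frame `x0, y0, x1, y1` in database units.
#' @export
gdsii_rectangles <- function(gds, top_name = "MUGRID") {
  top <- gds$cells[[top_name]]
  if (is.null(top)) stop("top structure '", top_name, "' not found")
  out <- list()
  poly_bbox <- function(p, dx = 0, dy = 0)
    c(min(p[, 1]) + dx, min(p[, 2]) + dy, max(p[, 1]) + dx, max(p[, 2]) + dy)
  for (p in top$polygons) out[[length(out) + 1L]] <- poly_bbox(p)
  for (k in seq_len(nrow(top$srefs))) {
    ref <- gds$cells[[top$srefs$name[k]]]
    if (is.null(ref)) stop("referenced structure '", top$srefs$name[k], "' not found")
    for (p in ref$polygons)
      out[[length(out) + 1L]] <- poly_bbox(p, top$srefs$x[k], top$srefs$y[k])
  }
  if (!length(out)) return(data.frame(x0 = numeric(0), y0 = numeric(0),
                                      x1 = numeric(0), y1 = numeric(0)))
  m <- do.call(rbind, out)
  data.frame(x0 = m[, 1], y0 = m[, 2], x1 = m[, 3], y1 = m[, 4])
}
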