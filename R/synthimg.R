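# Synthetic microscope imaging of grid layouts: a parametric camera model
# (pixel scale, in-plane rotation, polarity, Gaussian PSF, additive noise)
# over an optional substrate-deformation field. Stands in for real
# brightfield/darkfield/SEM micrographs in tests and demos.
#
# Conventions, used everywhere a pixel coordinate appears:
#  - physical frame: micrometres, y up;
#  - image frame: matrix [row, col], 1-based, row increases downward
#    (image row axis = -y physical axis);
#  - the image centre pixel ((rows+1)/2, (cols+1)/2) sees the physical
#    point `translation`;
#  - `rotation` is the stage-to-image rotation about the optical axis in
#    degrees: a physical +x unit vector maps to pixel direction
#    (d_col, d_row) = (cos r, sin r).

#' Parametric camera model for synthetic rendering
#'
#' @param pixel_size micrometres per pixel.
#' @param image_size `c(rows, cols)`.
#' @param rotation stage-to-image rotation, degrees.
#' @param translation physical position (um) of the image centre, `c(x, y)`.
#' @param polarity `"dark_features"` (features below background, as in
#'   brightfield) or `"bright_features"` (above, as in darkfield or
#'   secondary-electron SEM).
#' @param blur_sigma Gaussian PSF sigma in micrometres.
#' @param noise_sigma additive Gaussian noise sigma as a fraction of the
#'   dynamic range.
#' @param background background intensity fraction in \[0, 1\].
#' @param contrast feature amplitude as intensity fraction; feature pixels
#'   sit at `background +/- contrast` depending on polarity.
#' @param seed integer seed making the noise reproducible.
#' @return a `camera_model` list.
#' @export
camera_model <- function(pixel_size, image_size = c(512L, 512L), rotation = 0,
                         translation = c(0, 0),
                         polarity = c("bright_features", "dark_features"),
                         blur_sigma = 0, noise_sigma = 0,
                         background = 0.5, contrast = 0.4, seed = 1L) {
  polarity <- match.arg(polarity)
  stopifnot(pixel_size > 0, blur_sigma >= 0, noise_sigma >= 0,
            length(image_size) == 2L, all(image_size >= 1),
            background >= 0, background <= 1, contrast > 0)
  structure(list(pixel_size = pixel_size, image_size = as.integer(image_size),
                 rotation = rotation, translation = as.numeric(translation),
                 polarity = polarity, blur_sigma = blur_sigma,
                 noise_sigma = noise_sigma, background = background,
                 contrast = contrast, seed = as.integer(seed)),
            class = "camera_model")
}

#' Substrate deformation field
#'
#' Models the dimensional changes a substrate undergoes during sample
#' processing (swelling, shrinking, warping): `uniform_scale` applies one
#' isotropic scale factor, `anisotropic_scale` separate x/y factors,
#' `piecewise_affine` a table of affine maps over rectangular regions.
#'
#' @param model one of `"none"`, `"uniform_scale"`, `"anisotropic_scale"`,
#'   `"piecewise_affine"`.
#' @param sx,sy scale factors (> 0) for the scale models.
#' @param regions for `piecewise_affine`: data.frame with columns
#'   `x0, y0, x1, y1` (region, um) and `a11, a12, a21, a22, tx, ty` (affine
#'   applied to points in the region); regions must tile the layout extent.
#' @return a `deformation_field`.
#' @export
deformation_field <- function(model = c("none", "uniform_scale",
                                        "anisotropic_scale", "piecewise_affine"),
                              sx = 1, sy = sx, regions = NULL) {
  model <- match.arg(model)
  if (model %in% c("uniform_scale", "anisotropic_scale"))
    stopifnot(sx > 0, sy > 0)
  if (model == "uniform_scale") sy <- sx
  if (model == "piecewise_affine" && is.null(regions))
    stop("piecewise_affine needs a 'regions' table")
  structure(list(model = model, sx = sx, sy = sy, regions = regions),
            class = "deformation_field")
}

# apply deformation to n x 2 matrix of physical points
.deform_points <- function(p, deform) {
  if (is.null(deform) || deform$model == "none") return(p)
  if (deform$model %in% c("uniform_scale", "anisotropic_scale"))
    return(cbind(p[, 1] * deform$sx, p[, 2] * deform$sy))
  out <- p
  rg <- deform$regions
  for (i in seq_len(nrow(p))) {
    k <- which(p[i, 1] >= rg$x0 & p[i, 1] <= rg$x1 &
               p[i, 2] >= rg$y0 & p[i, 2] <= rg$y1)[1]
    if (is.na(k)) next
    out[i, ] <- c(rg$a11[k] * p[i, 1] + rg$a12[k] * p[i, 2] + rg$tx[k],
                  rg$a21[k] * p[i, 1] + rg$a22[k] * p[i, 2] + rg$ty[k])
  }
  out
}

# physical (um, n x 2) -> pixel (n x 2 matrix row, col), 1-based
.phys_to_pixel <- function(p, camera) {
  th <- camera$rotation * pi / 180
  dx <- p[, 1] - camera$translation[1]
  dy <- p[, 2] - camera$translation[2]
  u <- (cos(th) * dx + sin(th) * dy) / camera$pixel_size
  v <- (-sin(th) * dx + cos(th) * dy) / camera$pixel_size
  rc <- (camera$image_size[1] + 1) / 2
  cc <- (camera$image_size[2] + 1) / 2
  cbind(row = rc - v, col = cc + u)
}

# pixel (row, col) -> physical (um)
.pixel_to_phys <- function(rc_mat, camera) {
  th <- camera$rotation * pi / 180
  rc <- (camera$image_size[1] + 1) / 2
  cc <- (camera$image_size[2] + 1) / 2
  u <- rc_mat[, 2] - cc
  v <- rc - rc_mat[, 1]
  cbind(x = cos(th) * u * camera$pixel_size - sin(th) * v * camera$pixel_size +
          camera$translation[1],
        y = sin(th) * u * camera$pixel_size + cos(th) * v * camera$pixel_size +
          camera$translation[2])
}

#' Render a synthetic micrograph of a grid layout
#'
#' Every code rectangle is mapped through the deformation field and the
#' camera's stage-to-image similarity, rasterised with area-weighted
#' anti-aliasing (subpixel supersampling), convolved with the Gaussian PSF,
#' given the camera's polarity, and overlaid with additive Gaussian noise
#' from the camera seed. Deterministic for a fixed seed.
#'
#' @param layout a [generate_grid()] layout.
#' @param camera a [camera_model()].
#' @param deform a [deformation_field()] (default none).
#' @param supersample subpixel samples per axis for anti-aliasing.
#' @return numeric matrix `[row, col]` with values in \[0, 1\].
#' @export
render <- function(layout, camera, deform = deformation_field("none"),
                   supersample = 4L) {
  nr <- camera$image_size[1]; nc <- camera$image_size[2]
  cov <- matrix(0, nr, nc)
  off <- (seq_len(supersample) - 0.5) / supersample - 0.5
  pl <- layout$placements
  geoms <- new.env()
  # scale-model deformations keep rectangles axis-aligned in physical frame;
  # piecewise-affine is applied to rectangle corners (adequate when regions
  # are large relative to one code)
  for (k in seq_len(nrow(pl))) {
    key <- paste0(pl$x_index[k], "_", pl$y_index[k])
    geom <- encode(c(pl$x_index[k], pl$y_index[k]), layout$spec)
    r <- geom$rectangles
    corners0 <- cbind(pl$x_um[k] + r$x0, pl$y_um[k] + r$y0)
    corners1 <- cbind(pl$x_um[k] + r$x1, pl$y_um[k] + r$y1)
    d0 <- .deform_points(corners0, deform)
    d1 <- .deform_points(corners1, deform)
    for (i in seq_len(nrow(r))) {
      x0 <- min(d0[i, 1], d1[i, 1]); x1 <- max(d0[i, 1], d1[i, 1])
      y0 <- min(d0[i, 2], d1[i, 2]); y1 <- max(d0[i, 2], d1[i, 2])
      px <- .phys_to_pixel(rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1)), camera)
      r0 <- max(1L, floor(min(px[, 1]))); r1 <- min(nr, ceiling(max(px[, 1])))
      c0 <- max(1L, floor(min(px[, 2]))); c1 <- min(nc, ceiling(max(px[, 2])))
      if (r0 > r1 || c0 > c1) next
      rows <- r0:r1; cols <- c0:c1
      rr <- rep(rows, times = length(cols)); cc <- rep(cols, each = length(rows))
      acc <- numeric(length(rr))
      for (orow in off) for (ocol in off) {
        ph <- .pixel_to_phys(cbind(rr + orow, cc + ocol), camera)
        acc <- acc + (ph[, 1] >= x0 & ph[, 1] <= x1 & ph[, 2] >= y0 & ph[, 2] <= y1)
      }
      cov[cbind(rr, cc)] <- cov[cbind(rr, cc)] + acc / supersample^2
    }
  }
  cov[cov > 1] <- 1
  if (camera$blur_sigma > 0) {
    sig_px <- camera$blur_sigma / camera$pixel_size
    cov <- t(as.matrix(EBImage::gblur(t(cov), sigma = sig_px)))
  }
  img <- if (camera$polarity == "bright_features")
    camera$background + camera$contrast * cov
  else
    camera$background - camera$contrast * cov
  if (camera$noise_sigma > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(camera$seed)
    img <- img + matrix(stats::rnorm(nr * nc, 0, camera$noise_sigma), nr, nc)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  img
}

#' Ground-truth table for a rendered scene
#'
#' Exact projected pixel positions of the align-mark corner (the code-local
#' origin) of every code fully visible in the camera frame, with the true
#' in-image orientation -- the oracle for decoder tests.
#'
#' @param layout,camera,deform as in [render()].
#' @param margin_px border margin in pixels: a code counts as visible only
#'   when its whole bounding box projects at least this far inside the
#'   frame, keeping the sub-cell sampling support of downstream readers
#'   inside the image (default 3).
#' @return data.frame `x_index, y_index, px_row, px_col, orientation_deg`.
#'   Orientation is the stage-to-image rotation in degrees, modulo 360.
#' @export
ground_truth <- function(layout, camera, deform = deformation_field("none"),
                         margin_px = 3) {
  pl <- layout$placements
  fp <- footprint(layout$spec)
  out <- data.frame(x_index = integer(0), y_index = integer(0),
                    px_row = numeric(0), px_col = numeric(0),
                    orientation_deg = numeric(0))
  for (k in seq_len(nrow(pl))) {
    corners <- cbind(pl$x_um[k] + c(0, fp[1], fp[1], 0),
                     pl$y_um[k] + c(0, 0, fp[2], fp[2]))
    px <- .phys_to_pixel(.deform_points(corners, deform), camera)
    visible <- all(px[, 1] >= 1 + margin_px &
                   px[, 1] <= camera$image_size[1] - margin_px &
                   px[, 2] >= 1 + margin_px &
                   px[, 2] <= camera$image_size[2] - margin_px)
    if (!visible) next
    out <- rbind(out, data.frame(
      x_index = pl$x_index[k], y_index = pl$y_index[k],
      px_row = px[1, 1], px_col = px[1, 2],
      orientation_deg = camera$rotation %% 360))
  }
  out
}

#' Write a rendered image to PNG or TIFF
#'
#' @param img numeric matrix in \[0, 1\].
#' @param path output path; format chosen from the extension (`.png` for
#'   8-bit PNG, `.tif`/`.tiff` for 16-bit TIFF).
#' @return invisibly, `path`.
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = 16L)
  } else stop("unsupported image extension: ", ext)
  invisible(path)
}

#' Read a grayscale image from PNG or TIFF
#'
#' Multi-channel input is averaged to one channel; values are scaled to
#' \[0, 1\].
#'
#' @param path image file.
#' @return numeric matrix `[row, col]` in \[0, 1\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else stop("unsupported image extension: ", ext)
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE], c(1, 2), mean)
  img
}
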