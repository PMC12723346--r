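# Fiducial-driven co-registration of multimodal image pairs: match decoded
# codes between a fixed and a moving image, fit a similarity or affine
# transform by least squares, and resample the moving image into the fixed
# frame for an alpha-blended or channel-tinted overlay.
#
# Transforms act on homogeneous pixel coordinates (x = col, y = row,
# 1-based) as a 2 x 3 matrix mapping moving -> fixed.

#' Match detections between two images by grid coordinate
#'
#' Codes carry their own identity, so correspondence needs no geometric
#' search: detections decoding to the same grid coordinate in both images
#' are paired. Duplicate coordinates within one set keep the
#' higher-confidence detection (logged in the report).
#'
#' @param det_fixed,det_moving detection data.frames (see [detect_codes()]).
#' @return a `correspondence_set`: list with `pairs` (data.frame
#'   `x_index, y_index, fixed_row, fixed_col, moving_row, moving_col`) and
#'   `report` (unmatched/duplicate notes).
#' @export
match_by_code <- function(det_fixed, det_moving) {
  dedupe <- function(d, label) {
    if (!nrow(d)) return(list(d = d, note = character(0)))
    d <- d[order(-d$confidence), ]
    dup <- duplicated(d[, c("x_index", "y_index")])
    note <- if (any(dup))
      sprintf("%s: duplicate coordinate(s) %s resolved by confidence", label,
              paste(unique(paste0("(", d$x_index[dup], ",", d$y_index[dup], ")")),
                    collapse = " "))
    else character(0)
    list(d = d[!dup, ], note = note)
  }
  f <- dedupe(det_fixed, "fixed"); mv <- dedupe(det_moving, "moving")
  key_f <- paste(f$d$x_index, f$d$y_index)
  key_m <- paste(mv$d$x_index, mv$d$y_index)
  common <- intersect(key_f, key_m)
  if (length(common) < 2)
    stop("insufficient correspondences: fewer than 2 codes shared between the images")
  i <- match(common, key_f); j <- match(common, key_m)
  pairs <- data.frame(
    x_index = f$d$x_index[i], y_index = f$d$y_index[i],
    fixed_row = f$d$px_row[i], fixed_col = f$d$px_col[i],
    moving_row = mv$d$px_row[j], moving_col = mv$d$px_col[j])
  report <- c(f$note, mv$note,
              sprintf("matched %d codes; %d only in fixed, %d only in moving",
                      length(common), length(key_f) - length(common),
                      length(key_m) - length(common)))
  structure(list(pairs = pairs, report = report), class = "correspondence_set")
}

#' @export
print.correspondence_set <- function(x, ...) {
  cat(sprintf("correspondence_set: %d pairs\n", nrow(x$pairs)))
  for (r in x$report) cat(" ", r, "\n")
  invisible(x)
}

#' Estimate the moving-to-fixed image transform
#'
#' Least-squares fit of a similarity (rotation + isotropic scale +
#' translation; the default, matching the rotation-and-scaling alignment
#' used for fiducial-based overlays) or a full affine transform, mapping
#' moving-image pixels onto fixed-image pixels. The fit is exact (zero
#' residual) at the minimal pair count.
#'
#' @param corr a [match_by_code()] correspondence set, or its `pairs`
#'   data.frame.
#' @param model `"similarity"` or `"affine"`.
#' @return an `image_transform`: list with the 2 x 3 `matrix` (row-major
#'   action on `(x = col, y = row, 1)`), `model`, `theta_deg`, `scale`,
#'   `rms_residual` (px).
#' @export
estimate_transform <- function(corr, model = c("similarity", "affine")) {
  model <- match.arg(model)
  pairs <- if (inherits(corr, "correspondence_set")) corr$pairs else corr
  n <- nrow(pairs)
  if (n < if (model == "similarity") 2L else 3L)
    stop("not enough correspondences for model '", model, "'")
  # moving -> fixed in (x, y) = (col, row)
  Pm <- cbind(pairs$moving_col, pairs$moving_row)
  Pf <- cbind(pairs$fixed_col, pairs$fixed_row)
  if (model == "similarity") {
    zm <- complex(real = Pm[, 1], imaginary = Pm[, 2])
    zf <- complex(real = Pf[, 1], imaginary = Pf[, 2])
    zmc <- zm - mean(zm); zfc <- zf - mean(zf)
    denom <- sum(Mod(zmc)^2)
    if (denom == 0) stop("degenerate geometry: coincident points")
    w <- sum(Conj(zmc) * zfc) / denom
    t <- mean(zf) - w * mean(zm)
    M <- matrix(c(Re(w), -Im(w), Re(t),
                  Im(w), Re(w), Im(t)), 2, 3, byrow = TRUE)
    pred <- w * zm + t
    rms <- sqrt(mean(Mod(pred - zf)^2))
    theta <- Arg(w) * 180 / pi; sc <- Mod(w)
  } else {
    X <- cbind(Pm, 1)
    if (qr(X)$rank < 3) stop("rank error: correspondences are collinear")
    fx <- stats::lm.fit(X, Pf[, 1]); fy <- stats::lm.fit(X, Pf[, 2])
    M <- rbind(fx$coefficients[c(1, 2, 3)], fy$coefficients[c(1, 2, 3)])
    pred <- X %*% t(M)
    rms <- sqrt(mean(rowSums((pred - Pf)^2)))
    A <- M[, 1:2]
    sv <- svd(A)
    R <- sv$u %*% diag(c(1, det(sv$u %*% t(sv$v)))) %*% t(sv$v)
    theta <- atan2(R[2, 1], R[1, 1]) * 180 / pi
    sc <- exp(mean(log(sv$d)))
  }
  dimnames(M) <- NULL
  structure(list(model = model, matrix = M, theta_deg = theta %% 360,
                 scale = sc, rms_residual = rms),
            class = "image_transform")
}

#' @export
print.image_transform <- function(x, ...) {
  cat(sprintf("image_transform (%s): theta = %.4f deg, scale = %.6f, rms = %.4g px\n",
              x$model, x$theta_deg, x$scale, x$rms_residual))
  print(x$matrix)
  invisible(x)
}

# invert a 2x3 affine
.invert_transform <- function(M) {
  A <- M[, 1:2]
  if (abs(det(A)) < 1e-15) stop("transform is not invertible")
  Ai <- solve(A)
  cbind(Ai, -Ai %*% M[, 3])
}

#' Warp the moving image and blend it over the fixed image
#'
#' Resamples the moving image into the fixed frame (bilinear by default,
#' nearest-neighbour for label images) and composites
#' `(1 - alpha) * fixed + alpha * warped`; 50 percent transparency of the
#' top image is the conventional overlay. The tint mode renders the pair as
#' an RGB composite (fixed in grey, warped in a colour channel), the usual
#' presentation for fluorescence-on-electron-microscopy overlays.
#'
#' @param fixed,moving numeric matrices `[row, col]` in \[0, 1\].
#' @param transform an [estimate_transform()] result (moving -> fixed).
#' @param alpha opacity of the warped moving image (default 0.5).
#' @param resample `"bilinear"` or `"nearest"`.
#' @param tint `NULL` for grayscale blending, or one of
#'   `"red", "green", "magenta"` for a channel-tinted RGB composite.
#' @return list with `warped` (moving resampled in the fixed frame; NA
#'   outside its footprint) and `composite` (matrix, or rows x cols x 3
#'   array in tint mode).
#' @export
warp_and_overlay <- function(fixed, moving, transform, alpha = 0.5,
                             resample = c("bilinear", "nearest"), tint = NULL) {
  resample <- match.arg(resample)
  stopifnot(alpha >= 0, alpha <= 1)
  Mi <- .invert_transform(transform$matrix) # fixed -> moving
  nr <- nrow(fixed); nc <- ncol(fixed)
  g <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  src <- cbind(g$col, g$row, 1) %*% t(Mi) # (x, y) in moving
  sr <- src[, 2]; sc2 <- src[, 1]
  if (resample == "nearest") { sr <- round(sr); sc2 <- round(sc2) }
  vals <- .bilinear(moving, sr, sc2)
  warped <- matrix(vals, nr, nc)
  if (is.null(tint)) {
    w <- warped; w[is.na(w)] <- 0
    inside <- !is.na(warped)
    composite <- fixed
    composite[inside] <- (1 - alpha) * fixed[inside] + alpha * w[inside]
  } else {
    ch <- switch(tint, red = c(1, 0, 0), green = c(0, 1, 0),
                 magenta = c(1, 0, 1), stop("unknown tint: ", tint))
    w <- warped; w[is.na(w)] <- 0
    composite <- array(0, c(nr, nc, 3))
    for (k in 1:3)
      composite[, , k] <- pmin(1, (1 - alpha) * fixed + alpha * w * ch[k])
  }
  list(warped = warped, composite = composite)
}

#' Per-pair residual report for a fitted registration
#'
#' @param corr correspondence set or pairs data.frame.
#' @param transform fitted [estimate_transform()].
#' @param pixel_size optional micrometres per fixed-image pixel, to report
#'   residuals in physical units as well.
#' @return list with `residuals` (per-pair table, px and optionally um),
#'   `rms_px`, `max_px`.
#' @export
registration_report <- function(corr, transform, pixel_size = NULL) {
  pairs <- if (inherits(corr, "correspondence_set")) corr$pairs else corr
  M <- transform$matrix
  pred <- cbind(pairs$moving_col, pairs$moving_row, 1) %*% t(M)
  dx <- pred[, 1] - pairs$fixed_col
  dy <- pred[, 2] - pairs$fixed_row
  r <- sqrt(dx^2 + dy^2)
  tab <- data.frame(x_index = pairs$x_index, y_index = pairs$y_index,
                    residual_px = r)
  if (!is.null(pixel_size)) tab$residual_um <- r * pixel_size
  list(residuals = tab, rms_px = sqrt(mean(r^2)), max_px = max(r))
}

#' Serialize an image transform to JSON
#' @param transform an `image_transform`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(
    list(model = transform$model,
         matrix = as.vector(t(transform$matrix)), # row-major 2x3
         theta_deg = transform$theta_deg, scale = transform$scale,
         rms_residual = transform$rms_residual,
         convention = "maps moving (col,row,1) to fixed (col,row); row-major"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
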