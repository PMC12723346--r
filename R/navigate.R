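# Grid <-> instrument-stage navigation: calibrate a transform from anchor
# codes with known stage coordinates, predict stage positions of target
# codes, and report substrate-deformation metrics (scale factors).
#
# Grid physical positions are coordinate index x spacing, in micrometres.
# Stage units are whatever the instrument reports; they are declared by the
# user once per session and never converted silently.

#' Anchor table constructor
#'
#' An anchor pairs a decoded grid coordinate with the instrument stage
#' position read off while that code was centred.
#'
#' @param x_index,y_index integer grid indices.
#' @param stage_x,stage_y stage readings (instrument units).
#' @return data.frame with columns `x_index, y_index, stage_x, stage_y`.
#' @export
anchors <- function(x_index, y_index, stage_x, stage_y) {
  stopifnot(length(x_index) == length(y_index),
            length(stage_x) == length(x_index),
            length(stage_y) == length(x_index))
  a <- data.frame(x_index = as.integer(x_index), y_index = as.integer(y_index),
                  stage_x = stage_x, stage_y = stage_y)
  if (anyDuplicated(a[, c("x_index", "y_index")]))
    stop("anchors must have distinct grid coordinates")
  a
}

#' Read anchors from CSV
#' @param path CSV with columns `x_index, y_index, stage_x, stage_y`.
#' @return anchor data.frame.
#' @export
read_anchors <- function(path) {
  a <- utils::read.csv(path)
  anchors(a$x_index, a$y_index, a$stage_x, a$stage_y)
}

# Bowyer-Watson Delaunay triangulation; pts: n x 2. Returns m x 3 index
# matrix. Small-n use only (anchor sets).
.delaunay <- function(pts) {
  n <- nrow(pts)
  stopifnot(n >= 3)
  M <- max(abs(pts)) * 10 + 10
  sup <- rbind(c(-4 * M, -4 * M), c(4 * M, -4 * M), c(0, 4 * M))
  P <- rbind(sup, pts)
  tris <- list(c(1L, 2L, 3L))
  circum <- function(t) {
    a <- P[t[1], ]; b <- P[t[2], ]; c2 <- P[t[3], ]
    d <- 2 * (a[1] * (b[2] - c2[2]) + b[1] * (c2[2] - a[2]) + c2[1] * (a[2] - b[2]))
    if (abs(d) < 1e-12) return(c(Inf, Inf, Inf))
    ux <- ((a[1]^2 + a[2]^2) * (b[2] - c2[2]) + (b[1]^2 + b[2]^2) * (c2[2] - a[2]) +
           (c2[1]^2 + c2[2]^2) * (a[2] - b[2])) / d
    uy <- ((a[1]^2 + a[2]^2) * (c2[1] - b[1]) + (b[1]^2 + b[2]^2) * (a[1] - c2[1]) +
           (c2[1]^2 + c2[2]^2) * (b[1] - a[1])) / d
    c(ux, uy, (ux - a[1])^2 + (uy - a[2])^2)
  }
  cc <- list(circum(tris[[1]]))
  for (ip in 4:(n + 3)) {
    p <- P[ip, ]
    bad <- vapply(seq_along(tris), function(k) {
      (p[1] - cc[[k]][1])^2 + (p[2] - cc[[k]][2])^2 < cc[[k]][3] * (1 + 1e-12)
    }, logical(1))
    # boundary polygon of the bad-triangle cavity
    edges <- list()
    for (k in which(bad)) {
      t <- tris[[k]]
      for (e in list(t[c(1, 2)], t[c(2, 3)], t[c(3, 1)]))
        edges[[length(edges) + 1L]] <- sort(e)
    }
    if (length(edges)) {
      em <- do.call(rbind, edges)
      key <- paste(em[, 1], em[, 2])
      keep <- names(which(table(key) == 1L))
      tris <- tris[!bad]; cc <- cc[!bad]
      for (kk in keep) {
        e <- as.integer(strsplit(kk, " ")[[1]])
        tri <- c(e, ip)
        tris[[length(tris) + 1L]] <- tri
        cc[[length(cc) + 1L]] <- circum(tri)
      }
    }
  }
  out <- Filter(function(t) all(t > 3L), tris)
  if (!length(out)) stop("degenerate anchor geometry: no triangulation")
  do.call(rbind, lapply(out, function(t) t - 3L))
}

#' Calibrate the grid-to-stage mapping from anchor codes
#'
#' With exactly two anchors (the two-point calibration a user performs at
#' the instrument), the similarity transform is determined exactly: the
#' scale factor is the ratio of the stage distance to the grid physical
#' distance between the anchors -- the substrate-deformation metric --
#' and the rotation is the angle between the two displacement vectors.
#' More anchors give a least-squares fit with a reported RMS residual.
#' The affine model adds anisotropic scales (singular values of the linear
#' part); the piecewise-affine model interpolates exactly through >= 4
#' anchors over a Delaunay triangulation of the grid plane.
#'
#' @param anch anchor data.frame (see [anchors()]).
#' @param spacing inter-marker spacing, micrometres.
#' @param model `"similarity"`, `"affine"`, or `"piecewise_affine"`.
#' @param reflection logical; two anchors cannot distinguish a proper
#'   rotation from a mirrored view, so reflection is applied only when
#'   requested (see [detect_reflection()]).
#' @return a `stage_mapping` with fields `model, theta_deg, scale, sx, sy,
#'   shear_deg, tx, ty, reflection, rms_residual` (plus the fitted matrix).
#' @export
calibrate <- function(anch, spacing,
                      model = c("similarity", "affine", "piecewise_affine"),
                      reflection = FALSE) {
  model <- match.arg(model)
  n <- nrow(anch)
  need <- c(similarity = 2L, affine = 3L, piecewise_affine = 4L)[[model]]
  if (n < need) stop(sprintf("model '%s' needs at least %d anchors", model, need))
  P <- cbind(anch$x_index, anch$y_index) * spacing
  if (reflection) P[, 2] <- -P[, 2]
  Q <- cbind(anch$stage_x, anch$stage_y)
  if (any(duplicated(P))) stop("degenerate geometry: coincident anchors")

  if (model == "similarity") {
    zP <- complex(real = P[, 1], imaginary = P[, 2])
    zQ <- complex(real = Q[, 1], imaginary = Q[, 2])
    if (n == 2L) {
      w <- (zQ[2] - zQ[1]) / (zP[2] - zP[1])
      t <- zQ[1] - w * zP[1]
    } else { # least squares in the complex plane
      zPc <- zP - mean(zP); zQc <- zQ - mean(zQ)
      w <- sum(Conj(zPc) * zQc) / sum(Mod(zPc)^2)
      t <- mean(zQ) - w * mean(zP)
    }
    if (Mod(w) == 0) stop("degenerate geometry: zero scale")
    pred <- w * zP + t
    rms <- sqrt(mean(Mod(pred - zQ)^2))
    A <- Mod(w) * matrix(c(cos(Arg(w)), sin(Arg(w)), -sin(Arg(w)), cos(Arg(w))), 2, 2)
    m <- list(model = model, theta_deg = (Arg(w) * 180 / pi) %% 360,
              scale = Mod(w), sx = Mod(w), sy = Mod(w), shear_deg = 0,
              tx = Re(t), ty = Im(t), reflection = reflection,
              rms_residual = rms, A = A, spacing = spacing)
  } else if (model == "affine") {
    if (qr(cbind(1, P))$rank < 3) stop("rank error: anchors are collinear")
    fx <- stats::lm.fit(cbind(1, P), Q[, 1])
    fy <- stats::lm.fit(cbind(1, P), Q[, 2])
    A <- rbind(fx$coefficients[2:3], fy$coefficients[2:3])
    sv <- svd(A)
    # proper rotation from the polar decomposition, sign-corrected
    R <- sv$u %*% diag(c(1, det(sv$u %*% t(sv$v)))) %*% t(sv$v)
    theta <- atan2(R[2, 1], R[1, 1])
    # shear: departure of the transformed axes from orthogonality
    ax <- A %*% c(1, 0); ay <- A %*% c(0, 1)
    shear <- 90 - acos(sum(ax * ay) / sqrt(sum(ax^2) * sum(ay^2))) * 180 / pi
    pred <- cbind(1, P) %*% rbind(c(fx$coefficients[1], fy$coefficients[1]),
                                  t(A))
    rms <- sqrt(mean(rowSums((pred - Q)^2)))
    m <- list(model = model, theta_deg = (theta * 180 / pi) %% 360,
              scale = exp(mean(log(sv$d))), sx = sv$d[1], sy = sv$d[2],
              shear_deg = shear,
              tx = fx$coefficients[1], ty = fy$coefficients[1],
              reflection = reflection, rms_residual = rms, A = A,
              spacing = spacing)
  } else {
    if (qr(cbind(1, P))$rank < 3) stop("rank error: anchors are collinear")
    tri <- .delaunay(P)
    # per-triangle affine maps (exact interpolation at the anchors)
    pieces <- lapply(seq_len(nrow(tri)), function(k) {
      id <- tri[k, ]
      Pm <- cbind(1, P[id, , drop = FALSE])
      cfx <- solve(Pm, Q[id, 1]); cfy <- solve(Pm, Q[id, 2])
      list(idx = id, coef = rbind(cfx, cfy))
    })
    # global affine fallback outside the anchor hull
    glob <- calibrate(anch, spacing, model = "affine", reflection = reflection)
    m <- list(model = model, theta_deg = glob$theta_deg, scale = glob$scale,
              sx = glob$sx, sy = glob$sy, shear_deg = glob$shear_deg,
              tx = glob$tx, ty = glob$ty, reflection = reflection,
              rms_residual = 0, A = glob$A, spacing = spacing,
              tri = tri, P = P, Q = Q, pieces = pieces, fallback = glob)
  }
  m$anchors <- anch
  class(m) <- "stage_mapping"
  m
}

#' @export
print.stage_mapping <- function(x, ...) {
  cat(sprintf(
    "stage_mapping (%s): theta = %.4f deg, scale = %.6f (sx %.6f, sy %.6f), t = (%.4g, %.4g)\n",
    x$model, x$theta_deg, x$scale, x$sx, x$sy, x$tx, x$ty))
  cat(sprintf("  reflection: %s, rms residual: %.4g\n", x$reflection, x$rms_residual))
  invisible(x)
}

# barycentric point-in-triangle lookup; returns piece index or NA
.find_piece <- function(mapping, p) {
  for (k in seq_len(nrow(mapping$tri))) {
    id <- mapping$tri[k, ]
    a <- mapping$P[id[1], ]; b <- mapping$P[id[2], ]; c2 <- mapping$P[id[3], ]
    d <- (b[2] - c2[2]) * (a[1] - c2[1]) + (c2[1] - b[1]) * (a[2] - c2[2])
    if (abs(d) < 1e-12) next
    l1 <- ((b[2] - c2[2]) * (p[1] - c2[1]) + (c2[1] - b[1]) * (p[2] - c2[2])) / d
    l2 <- ((c2[2] - a[2]) * (p[1] - c2[1]) + (a[1] - c2[1]) * (p[2] - c2[2])) / d
    l3 <- 1 - l1 - l2
    if (l1 >= -1e-9 && l2 >= -1e-9 && l3 >= -1e-9) return(k)
  }
  NA_integer_
}

#' Predict the stage position of a grid coordinate
#'
#' @param mapping a [calibrate()]d `stage_mapping`.
#' @param coord length-2 vector `c(x_index, y_index)` (or a 2-column
#'   matrix of coordinates).
#' @param spacing inter-marker spacing, micrometres (defaults to the value
#'   stored at calibration).
#' @return stage position(s): numeric length-2 vector or n x 2 matrix.
#' @export
grid_to_stage <- function(mapping, coord, spacing = mapping$spacing) {
  cm <- if (is.matrix(coord)) coord else matrix(coord, ncol = 2)
  P <- cm * spacing
  if (mapping$reflection) P[, 2] <- -P[, 2]
  out <- matrix(NA_real_, nrow(P), 2)
  for (i in seq_len(nrow(P))) {
    p <- P[i, ]
    if (mapping$model == "piecewise_affine") {
      k <- .find_piece(mapping, p)
      if (is.na(k)) {
        g <- mapping$fallback
        out[i, ] <- as.numeric(g$A %*% p) + c(g$tx, g$ty)
      } else {
        cf <- mapping$pieces[[k]]$coef
        out[i, ] <- as.numeric(cf %*% c(1, p))
      }
    } else {
      out[i, ] <- as.numeric(mapping$A %*% p) + c(mapping$tx, mapping$ty)
    }
  }
  if (!is.matrix(coord)) out <- drop(out)
  out
}

#' Invert the mapping: find the grid coordinate nearest a stage position
#'
#' Inverse-maps the stage position to the grid physical frame, divides by
#' the spacing and rounds to the nearest integers; exact halves round
#' toward the lower index (documented tie-break). The residual is the
#' stage-frame distance between the given position and the mapped position
#' of the returned coordinate.
#'
#' @param mapping a `stage_mapping` with invertible linear part.
#' @param position stage position `c(x, y)`.
#' @param spacing inter-marker spacing, micrometres.
#' @return list with `coord` (integer x/y indices) and `residual` (stage
#'   units).
#' @export
stage_to_grid <- function(mapping, position, spacing = mapping$spacing) {
  A <- mapping$A
  if (abs(det(A)) < 1e-15) stop("singular mapping: linear part not invertible")
  if (mapping$model == "piecewise_affine") {
    # search the triangle whose stage-side image contains the position
    p_est <- NULL
    for (k in seq_len(length(mapping$pieces))) {
      cf <- mapping$pieces[[k]]$coef # (1, px, py) -> stage
      Ak <- cf[, 2:3]
      if (abs(det(Ak)) < 1e-15) next
      pk <- solve(Ak, position - cf[, 1])
      if (!is.na(.find_piece(mapping, pk)) && .find_piece(mapping, pk) == k) {
        p_est <- pk; break
      }
    }
    if (is.null(p_est)) p_est <- solve(A, position - c(mapping$tx, mapping$ty))
  } else {
    p_est <- solve(A, position - c(mapping$tx, mapping$ty))
  }
  if (mapping$reflection) p_est[2] <- -p_est[2]
  idx <- ceiling(p_est / spacing - 0.5) # round, halves toward lower index
  idx <- pmax(idx, 0)
  pred <- grid_to_stage(mapping, idx, spacing)
  list(coord = c(x_index = as.integer(idx[1]), y_index = as.integer(idx[2])),
       residual = sqrt(sum((pred - position)^2)))
}

#' Deformation report for an affine or piecewise mapping
#'
#' Decomposes the linear part by SVD into anisotropic scale factors and a
#' proper rotation, reports the shear angle, and tabulates per-anchor
#' residuals for outlier spotting. Scale factors different from 1 quantify
#' substrate swelling or shrinkage; unequal factors indicate anisotropic
#' deformation.
#'
#' @param mapping a `stage_mapping` fitted from >= 3 anchors.
#' @return list with `sx, sy, theta_deg, shear_deg` and `residuals`
#'   (data.frame `x_index, y_index, residual`).
#' @export
deformation_report <- function(mapping) {
  if (!mapping$model %in% c("affine", "piecewise_affine"))
    stop("deformation_report needs an affine or piecewise_affine mapping")
  anch <- mapping$anchors
  pred <- grid_to_stage(
    if (mapping$model == "piecewise_affine") mapping$fallback else mapping,
    cbind(anch$x_index, anch$y_index))
  res <- sqrt(rowSums((pred - cbind(anch$stage_x, anch$stage_y))^2))
  list(sx = mapping$sx, sy = mapping$sy, theta_deg = mapping$theta_deg,
       shear_deg = mapping$shear_deg,
       residuals = data.frame(x_index = anch$x_index, y_index = anch$y_index,
                              residual = res))
}

#' Detect a mirrored view from decoded codes
#'
#' The binary/ternary L-layout is chiral, so a decoded scene reveals
#' whether the instrument view is mirrored relative to the grid: for at
#' least three non-collinear detections, the signed area of the decoded
#' coordinates must match the signed area of their pixel positions (in a
#' y-up pixel frame). Use the result as the `reflection` flag for
#' [calibrate()].
#'
#' @param detections data.frame from [detect_codes()] with >= 3
#'   non-collinear codes.
#' @return logical: `TRUE` when the view is mirrored.
#' @export
detect_reflection <- function(detections) {
  if (nrow(detections) < 3) stop("need >= 3 detections to assess reflection")
  K <- cbind(detections$x_index, detections$y_index)
  Q <- cbind(detections$px_col, -detections$px_row)
  sgn_area <- function(M) {
    v1 <- M[2, ] - M[1, ]; v2 <- M[3, ] - M[1, ]
    sign(v1[1] * v2[2] - v1[2] * v2[1])
  }
  # first non-collinear triple
  for (i in 3:nrow(K)) {
    sK <- sgn_area(K[c(1, 2, i), ]); sQ <- sgn_area(Q[c(1, 2, i), ])
    if (sK != 0 && sQ != 0) return(sK != sQ)
  }
  stop("all detections are collinear; reflection is undetermined")
}

#' Serialize a stage mapping to JSON
#' @param mapping a `stage_mapping`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_mapping_json <- function(mapping, path) {
  jsonlite::write_json(
    list(model = mapping$model, theta_deg = mapping$theta_deg,
         scale = mapping$scale, sx = mapping$sx, sy = mapping$sy,
         shear_deg = mapping$shear_deg, tx = mapping$tx, ty = mapping$ty,
         reflection = mapping$reflection, rms_residual = mapping$rms_residual,
         spacing = mapping$spacing),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
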