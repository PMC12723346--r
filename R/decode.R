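# Machine-vision decoding of grid codes from grayscale images.
#
# Pipeline: polarity normalisation (Otsu), connected components, proximity
# clustering of components into code candidates, orientation from the
# minimum-area bounding rectangle (the chiral L-layout disambiguates the
# four 90-degree choices), lattice rectification refined by direct search,
# per-cell intensity sampling against a local background reference, symbol
# decode, confidence scoring, and a lattice-consistency filter.

#' Hints guiding code detection
#'
#' @param spec the [grid_spec()] the image is expected to contain; only the
#'   binary and ternary L-layout schemes are supported for full-image
#'   detection (see [read_code_crop()] for decimal/planet symbols).
#' @param approx_pixel_size approximate micrometres per pixel; errors up to
#'   about +/-50 percent are tolerated.
#' @param polarity `"auto"`, `"dark_features"` or `"bright_features"`.
#' @param min_confidence detections below this confidence are dropped
#'   (default 0.8).
#' @return a `decode_hints` list.
#' @export
decode_hints <- function(spec, approx_pixel_size,
                         polarity = c("auto", "dark_features", "bright_features"),
                         min_confidence = 0.8) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(spec, "grid_spec"), approx_pixel_size > 0,
            min_confidence >= 0, min_confidence <= 1)
  structure(list(spec = spec, approx_pixel_size = approx_pixel_size,
                 polarity = polarity, min_confidence = min_confidence),
            class = "decode_hints")
}

# vectorised bilinear sampling; out-of-bounds -> NA
.bilinear <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 + 1 <= nr & c0 + 1 <= nc
  out <- rep(NA_real_, length(r))
  if (any(ok)) {
    i00 <- cbind(r0[ok], c0[ok]); i10 <- cbind(r0[ok] + 1, c0[ok])
    i01 <- cbind(r0[ok], c0[ok] + 1); i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
    out[ok] <- img[i00] * (1 - fr[ok]) * (1 - fc[ok]) +
      img[i10] * fr[ok] * (1 - fc[ok]) +
      img[i01] * (1 - fr[ok]) * fc[ok] +
      img[i11] * fr[ok] * fc[ok]
  }
  out
}

# candidate in-plane angles (radians, mod pi/2) for one component cluster:
# the minimum-area bounding-rectangle angle (reliable for compact or merged
# masks with straight edges), and, when several components are present, the
# distance-weighted circular mean of pairwise centroid directions --
# component centroids sit on the arm axes, which stays true when blur turns
# the mask into disconnected blobs.
.cluster_angles <- function(pts, cmp) {
  a <- .minarea_angle(pts)
  out <- a
  ids <- unique(cmp)
  if (length(ids) >= 2) {
    cr <- tapply(pts[, 1], cmp, mean)
    cc <- tapply(pts[, 2], cmp, mean)
    z <- 0
    for (i in 1:(length(cr) - 1)) for (j in (i + 1):length(cr)) {
      dr <- cr[j] - cr[i]; dc <- cc[j] - cc[i]
      w <- sqrt(dr^2 + dc^2)
      if (w <= 0) next
      z <- z + w * exp(4i * atan2(dr, dc))
    }
    if (Mod(z) > 0) {
      a2 <- (Arg(z) / 4) %% (pi / 2)
      d <- abs(a2 - a)
      if (min(d, pi / 2 - d) > 3 * pi / 180) out <- c(out, a2)
    }
  }
  out
}

# angle (radians, mod pi/2) of the minimum-area bounding rectangle of a
# point set, via rotating the convex hull through each hull-edge direction
.minarea_angle <- function(pts) {
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts[, 2], pts[, 1]) # (x = col, y = row)
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  best <- c(Inf, 0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- atan2(hp[j, 1] - hp[i, 1], hp[j, 2] - hp[i, 2]) %% (pi / 2)
    u <- cos(a) * hp[, 2] + sin(a) * hp[, 1]
    v <- -sin(a) * hp[, 2] + cos(a) * hp[, 1]
    area <- (max(u) - min(u)) * (max(v) - min(v))
    if (area < best[1]) best <- c(area, a)
  }
  best[2]
}

# code-frame coords of pixel offsets under in-image rotation theta:
# code +x maps to pixel direction (d_col, d_row) = (cos th, sin th);
# the (u, v) <-> (d_col, d_row) map is symmetric orthogonal (det -1,
# absorbing the row-axis flip) and is its own inverse.
.to_code_frame <- function(dc, dr, th)
  cbind(u = cos(th) * dc + sin(th) * dr, v = sin(th) * dc - cos(th) * dr)
.from_code_frame <- function(u, v, th)
  cbind(dc = cos(th) * u + sin(th) * v, dr = sin(th) * u - cos(th) * v)

# mean image intensity over a 3x3 sample stencil inside each lattice cell;
# cells: data.frame i, j (0-based); returns vector of cell means
.sample_cells <- function(img, ox, oy, s, th, cells) {
  offs <- expand.grid(du = c(-0.25, 0, 0.25), dv = c(-0.25, 0, 0.25))
  m <- numeric(nrow(cells))
  u <- rep(cells$i + 0.5, each = nrow(offs)) + offs$du
  v <- rep(cells$j + 0.5, each = nrow(offs)) + offs$dv
  d <- .from_code_frame(u * s, v * s, th)
  vals <- .bilinear(img, oy + d[, 2], ox + d[, 1])
  colMeans(matrix(vals, nrow = nrow(offs)))
}

# Lattice-pitch cost for one cluster in its code frame. Difference
# families, each relative to its own minimum so that the symmetric dilation
# bias of blur + thresholding cancels: component-centre differences fall on
# the half-integer cell lattice, start-edge and end-edge differences on the
# integer lattice (which breaks pitch aliases that centres alone admit).
# Only straight single-run components are used -- the centre of a 1 x k run
# lies on the half-integer lattice; L-shaped merges do not. A pitch that
# would imply more cells than the lattice holds is rejected. Returns NULL
# when the cluster offers fewer than two usable components.
.lattice_cost_fun <- function(uv, comp, s_ref, n, use_width = TRUE) {
  cu <- tapply(uv[, 1], comp, mean); cv <- tapply(uv[, 2], comp, mean)
  su <- tapply(uv[, 1], comp, min); eu <- tapply(uv[, 1], comp, max)
  sv <- tapply(uv[, 2], comp, min); ev <- tapply(uv[, 2], comp, max)
  thick <- pmin(eu - su, ev - sv)
  # straight single-run components: thin in one direction, judged both
  # against the scale estimate and against the thinnest component (the
  # latter is robust when the scale estimate is biased by heavy blur)
  straight <- thick <= pmax(1.5 * s_ref, 1.35 * min(thick))
  if (sum(straight) < 2) return(NULL)
  # component extents must be integer cell counts minus one shared
  # erosion/dilation offset; a pitch alias cannot satisfy a mixture of
  # single-cell and multi-cell runs with a single offset
  wall <- c((eu - su)[straight], (ev - sv)[straight]) + 1 # pixel extents
  width_cost <- function(sc) {
    if (!use_width) return(NULL)
    kw <- pmax(1, round(wall / sc))
    for (it in 1:2) {
      delta <- stats::median(kw * sc - wall) / 2
      kw <- pmax(1, round((wall + 2 * delta) / sc))
    }
    delta <- stats::median(kw * sc - wall) / 2
    if (abs(delta) > 0.4 * sc) return(Inf)
    mean(abs(wall + 2 * delta - kw * sc)) / sc
  }
  fam <- list(
    list(d = c(cu[straight], cv[straight]), step = 0.5),
    list(d = c(su[straight], sv[straight]), step = 1),
    list(d = c(eu[straight], ev[straight]), step = 1))
  half <- sum(straight)
  rel <- function(x) c(x[1:half] - min(x[1:half]),
                       x[-(1:half)] - min(x[-(1:half)]))
  ext <- max(max(uv[, 1]) - min(uv[, 1]), max(uv[, 2]) - min(uv[, 2]))
  cost1 <- function(d, sc, step) {
    k <- round(d / (sc * step)) * step
    if (any(k > n + 0.5)) return(Inf)
    mean(abs(d - k * sc)) / sc
  }
  list(
    cost = function(sc) {
      if (ext / sc > n + 1.25) return(Inf)
      parts <- vapply(fam, function(fm) cost1(rel(fm$d), sc, fm$step), numeric(1))
      wc <- width_cost(sc)
      mean(c(parts, wc))
    },
    polish = function(s) {
      for (it in 1:3) {
        k <- unlist(lapply(fam, function(fm) round(rel(fm$d) / (s * fm$step)) * fm$step))
        d <- unlist(lapply(fam, function(fm) rel(fm$d)))
        if (sum(k^2) > 0 && is.finite(sum(k * d) / sum(k^2)))
          s <- sum(k * d) / sum(k^2)
      }
      s
    })
}

# drawn rectangles of one L-layout symbol in cell units: (u0, u1, v0, v1)
.code_rects <- function(spec, xs, ys) {
  n <- spec$symbols_per_axis
  ff <- spec$fill_factor
  lo <- (1 - ff) / 2; hi <- 1 - lo
  rects <- list(c(lo, hi, lo, hi)) # align mark
  for (k in seq_len(n)) {
    if (spec$scheme == "ternary") {
      if (xs[k] == 2) rects <- c(rects, list(c(k + lo, k + hi, lo, hi)))
      if (xs[k] == 1) rects <- c(rects, list(c(k + 0.5 - ff / 4, k + 0.5 + ff / 4, lo, hi)))
      if (ys[k] == 2) rects <- c(rects, list(c(lo, hi, k + lo, k + hi)))
      if (ys[k] == 1) rects <- c(rects, list(c(lo, hi, k + 0.5 - ff / 4, k + 0.5 + ff / 4)))
    } else {
      if (xs[k] == 1) rects <- c(rects, list(c(k + lo, k + hi, lo, hi)))
      if (ys[k] == 1) rects <- c(rects, list(c(lo, hi, k + lo, k + hi)))
    }
  }
  rects
}

# predicted stencil-mean of each lattice cell under the Gaussian-blurred
# template (cell units); cells: data.frame i, j; sigma in cell units
.predict_cell_means <- function(rects, sigma, cells) {
  offs <- expand.grid(du = c(-0.25, 0, 0.25), dv = c(-0.25, 0, 0.25))
  u <- rep(cells$i + 0.5, each = nrow(offs)) + offs$du
  v <- rep(cells$j + 0.5, each = nrow(offs)) + offs$dv
  pred <- 0
  for (rc in rects)
    pred <- pred +
      (stats::pnorm((u - rc[1]) / sigma) - stats::pnorm((u - rc[2]) / sigma)) *
      (stats::pnorm((v - rc[3]) / sigma) - stats::pnorm((v - rc[4]) / sigma))
  colMeans(matrix(pred, nrow = nrow(offs)))
}

# Normalised cross-correlation between the image and the ideal rendering
# of a decoded symbol at a candidate lattice geometry. Dense sampling
# (3 per cell, extending half a cell beyond the lattice) makes the score
# sensitive to feature widths and edge positions, which the cell-centre
# reads are blind to -- this is what arbitrates between aliased pitch fits.
.pattern_ncc <- function(img, ox, oy, s, th, spec, xs, ys, sign_fg) {
  n <- spec$symbols_per_axis
  ff <- spec$fill_factor
  g <- seq(-0.5, n + 1.5, by = 1 / 3)
  gr <- expand.grid(u = g, v = g)
  d <- .from_code_frame(gr$u * s, gr$v * s, th)
  vals <- .bilinear(img, oy + d[, 2], ox + d[, 1])
  ok <- !is.na(vals)
  if (sum(ok) < 20) return(0)
  v <- sign_fg * vals[ok]
  if (stats::sd(v) == 0) return(0)
  rects <- .code_rects(spec, xs, ys)
  # the image is PSF-blurred, so correlate against the analytically blurred
  # template (separable Gaussian convolution of rectangles), maximised over
  # a small grid of nuisance blur widths (cell units)
  u <- gr$u[ok]; v2 <- gr$v[ok]
  best <- 0
  for (sig in c(0.04, 0.1, 0.2, 0.35, 0.5)) {
    pred <- 0
    for (rc in rects)
      pred <- pred +
        (stats::pnorm((u - rc[1]) / sig) - stats::pnorm((u - rc[2]) / sig)) *
        (stats::pnorm((v2 - rc[3]) / sig) - stats::pnorm((v2 - rc[4]) / sig))
    if (stats::sd(pred) == 0) next
    best <- max(best, stats::cor(v, pred))
  }
  best
}

# Blur-invariant feature-size estimate from isolated single-cell
# components. Two noise-robust observables of a Gaussian-blurred square --
# the peak-to-flux ratio and the half-peak area -- are matched against a
# lookup table over (feature size, blur width); the blur width is a
# nuisance parameter. Returns NA when no isolated single-cell component
# yields a usable estimate.
.flux_feature_size <- function(sm, bg, sign_fg, rows, cols, labs, keep, s0) {
  nm <- as.character(keep)
  cen_r <- tapply(rows, labs, mean)[nm]; cen_c <- tapply(cols, labs, mean)[nm]
  bw <- (tapply(cols, labs, max) - tapply(cols, labs, min))[nm]
  bh <- (tapply(rows, labs, max) - tapply(rows, labs, min))[nm]
  # near-square blobs only: mask dilation can swell a single cell well
  # beyond its nominal size, but runs of 2+ cells stay clearly oblong
  single <- pmax(bw, bh) <= 2.3 * s0 & abs(bw - bh) <= 0.5 * s0
  if (!any(single)) return(list(f = NA_real_, sigma = NA_real_))
  # lookup table of observables, computed over the same finite window as
  # the measurement so tail truncation is modelled rather than a bias
  fg <- seq(0.35, 1.9, by = 0.05) * s0
  sg <- seq(0.05, 0.8, by = 0.05) * s0
  par <- expand.grid(f = fg, sig = sg)
  step <- s0 / 12
  R <- round(1.5 * s0)
  x <- seq(-R, R, by = step)
  tab <- t(apply(par, 1, function(p) {
    prof <- stats::pnorm((x + p[1] / 2) / p[2]) - stats::pnorm((x - p[1] / 2) / p[2])
    pk <- max(prof)^2
    c(pf = pk / (sum(prof)^2 * step^2),
      ah = sum(outer(prof, prof) > pk / 2) * step^2)
  }))
  ests <- numeric(0); sigs <- numeric(0)
  for (i in which(single)) {
    d2 <- sqrt((cen_r - cen_r[i])^2 + (cen_c - cen_c[i])^2)
    d2 <- d2[d2 > 1e-9]
    if (length(d2) && min(d2) < 2.0 * s0) next # not isolated
    rr <- (round(cen_r[i]) - R):(round(cen_r[i]) + R)
    cc <- (round(cen_c[i]) - R):(round(cen_c[i]) + R)
    if (min(rr) < 1 || min(cc) < 1 || max(rr) > nrow(sm) || max(cc) > ncol(sm)) next
    w <- sign_fg * (sm[rr, cc] - bg)
    FF <- sum(w)
    if (FF <= 0) next
    P <- max(w)
    ah <- sum(w > P / 2)
    err <- log(pmax(tab[, "pf"], 1e-12) / (P / FF))^2 + log(tab[, "ah"] / ah)^2
    k <- which.min(err)
    fh <- par$f[k]
    if (fh <= 0.4 * s0 || fh >= 1.8 * s0) next # pinned at the table edge
    ests <- c(ests, fh); sigs <- c(sigs, par$sig[k])
  }
  if (!length(ests)) list(f = NA_real_, sigma = NA_real_)
  else list(f = stats::median(ests), sigma = stats::median(sigs))
}

# Attempt to decode one component cluster at one orientation candidate.
# pts: cluster pixel coords (row, col); comp: component id per pixel.
# Returns NULL or a detection row.
#
# Rectification is anchored structurally: the pitch comes from the shared
# scene estimate (refined within a narrow band on this cluster's component
# lattice), the origin from the pixel extent and from the corner
# component's centroid (which is unbiased under symmetric mask dilation).
# Symbols are then read against the Gaussian-blurred template: predicted
# cell means under each bit hypothesis, with gain/offset fitted per
# cluster, iterated to a fixed point. A cluster whose pixels are not
# explained by the decoded pattern (poor coverage) triggers a joint rescue
# fit of origin and pitch before the candidate is rejected.
.decode_candidate <- function(img, pts, comp, th, s0, spec, sign_fg,
                              s_band = 0.04, sigma_px = NA_real_,
                              rescue = FALSE) {
  n <- spec$symbols_per_axis
  arm <- data.frame(i = c(1:n, rep(0, n)), j = c(rep(0, n), 1:n))
  interior <- expand.grid(i = 1:n, j = 1:n)
  cells <- rbind(data.frame(i = 0, j = 0), arm, interior)
  uv <- .to_code_frame(pts[, 2], pts[, 1], th)
  n_arm <- nrow(arm)
  i_arm <- 2:(1 + n_arm)
  i_int <- (2 + n_arm):nrow(cells)
  dbg <- function(why) {
    if (isTRUE(getOption("gridcodes.debug2")))
      message(sprintf("  cand th=%.1f: %s", (th * 180 / pi) %% 360, why))
    NULL
  }

  # pitch: narrow refinement of the scene estimate on this cluster
  lat <- .lattice_cost_fun(uv, comp, s0, n, use_width = spec$scheme != "ternary")
  s <- s0
  if (!is.null(lat)) {
    grid <- s0 * seq(1 / (1 + s_band), 1 + s_band, length.out = 9)
    cc <- vapply(grid, lat$cost, numeric(1))
    if (any(is.finite(cc))) {
      s <- grid[which.min(cc)]
      # the regression at locked-in integer assignments may legitimately
      # land outside the candidate band; clamp only at the alias distance
      s_new <- lat$polish(s)
      if (is.finite(s_new))
        s <- min(max(s_new, s0 / 1.12), s0 * 1.12)
    }
  }

  # origin starts: pixel extent, and the corner component centroid offset
  # by half its run length (dilation-invariant)
  o_img <- .from_code_frame(min(uv[, 1]) - 0.5, min(uv[, 2]) - 0.5, th)
  cu_c <- tapply(uv[, 1], comp, mean); cv_c <- tapply(uv[, 2], comp, mean)
  su_c <- tapply(uv[, 1], comp, min); eu_c <- tapply(uv[, 1], comp, max)
  sv_c <- tapply(uv[, 2], comp, min); ev_c <- tapply(uv[, 2], comp, max)
  ic <- which.min(cu_c + cv_c)
  len_u <- max(1, round((eu_c[ic] - su_c[ic] + 1) / s - 0.4))
  len_v <- max(1, round((ev_c[ic] - sv_c[ic] + 1) / s - 0.4))
  o_img2 <- .from_code_frame(cu_c[ic] - len_u * s / 2, cv_c[ic] - len_v * s / 2, th)

  # blur width for the template, in cell units
  lv0 <- if (spec$scheme == "ternary") c(0, 0.5, 1) else c(0, 1)
  levels_n <- if (spec$scheme == "ternary") 2L else 1L
  self_cell <- data.frame(i = 0, j = 0)
  sigma_of <- function(sv) max(0.06, if (is.finite(sigma_px)) sigma_px / sv else 0.15)

  # model read at a given geometry: initial threshold guess, then iterate
  # template-based symbol decisions to a fixed point
  read_model <- function(ox, oy, sv) {
    m <- .sample_cells(img, ox, oy, sv, th, cells)
    # the align mark and both arms must be sampled, but empty interior
    # cells are allowed to fall outside the frame (a code sitting near a
    # corner); they are simply excluded from the background and residual
    if (anyNA(m[c(1L, i_arm)])) return(NULL)
    if (sum(!is.na(m[i_int])) < 12L) return(NULL)
    fg <- m[1]
    bg <- stats::median(m[i_int], na.rm = TRUE)
    if (sign_fg * (fg - bg) < 0.04) return(NULL)
    # the template blur width is itself uncertain (the scene estimate can
    # be badly off for an individual cluster, and an overestimate flattens
    # the template until spill-over reads as set bits); choose it by
    # residual over a small grid
    sig_set <- sort(unique(pmin(pmax(c(sigma_of(sv), 0.08, 0.2, 0.35), 0.06), 0.55)))
    outs <- lapply(sig_set, function(sig) .read_model_at(m, fg, bg, sig, sv, ox, oy))
    ok <- !vapply(outs, is.null, logical(1))
    if (!any(ok)) return(NULL)
    outs <- outs[ok]
    outs[[which.min(vapply(outs, function(o) o$resid, numeric(1)))]]
  }
  .read_model_at <- function(m, fg, bg, sig, sv, ox, oy) {
    t0 <- (m - bg) / (fg - bg)
    sym <- vapply(t0[i_arm], function(x) which.min(abs(x - lv0)) - 1L, integer(1))
    c_full <- .predict_cell_means(list(c((1 - spec$fill_factor) / 2,
                                         (1 + spec$fill_factor) / 2,
                                         (1 - spec$fill_factor) / 2,
                                         (1 + spec$fill_factor) / 2)), sig, self_cell)
    c_half <- if (spec$scheme == "ternary")
      .predict_cell_means(list(c(0.5 - spec$fill_factor / 4,
                                 0.5 + spec$fill_factor / 4,
                                 (1 - spec$fill_factor) / 2,
                                 (1 + spec$fill_factor) / 2)), sig, self_cell)
    else NULL
    self_of <- function(sv2) {
      if (sv2 == 0L) 0 else if (spec$scheme == "ternary" && sv2 == 1L) c_half else c_full
    }
    a_fit <- 0; b_fit <- sign_fg; pred <- NULL; t_model <- t0
    for (iter in 1:3) {
      pred <- .predict_cell_means(.code_rects(spec, sym[1:n], sym[(n + 1):(2 * n)]),
                                  sig, cells)
      val <- !is.na(m)
      vp <- stats::var(pred[val])
      if (!is.finite(vp) || vp <= 0) return(NULL)
      b_fit <- stats::cov(m[val], pred[val]) / vp
      a_fit <- mean(m[val]) - b_fit * mean(pred[val])
      if (sign_fg * b_fit < 0.04) return(NULL)
      t_model <- (m - a_fit) / b_fit
      new_sym <- sym
      for (k in seq_len(2 * n)) {
        base <- pred[i_arm][k] - self_of(sym[k])
        d <- vapply(0:levels_n, function(sv2) abs(t_model[i_arm][k] - (base + self_of(sv2))),
                    numeric(1))
        new_sym[k] <- (0:levels_n)[which.min(d)]
      }
      if (all(new_sym == sym)) break
      sym <- new_sym
    }
    pred <- .predict_cell_means(.code_rects(spec, sym[1:n], sym[(n + 1):(2 * n)]),
                                sig, cells)
    resid <- mean(abs(t_model - pred), na.rm = TRUE)
    # coverage: fraction of cluster pixels lying in (or within 0.3 cells
    # of) cells decoded as filled -- unexplained mask pixels signal a
    # mis-anchored lattice
    filled <- matrix(FALSE, n + 1, n + 1)
    filled[1, 1] <- TRUE
    for (k in 1:n) {
      if (sym[k] > 0) filled[k + 1, 1] <- TRUE
      if (sym[n + k] > 0) filled[1, k + 1] <- TRUE
    }
    o_fit <- .to_code_frame(ox, oy, th)
    ui <- (uv[, 1] - o_fit[1]) / sv; vj <- (uv[, 2] - o_fit[2]) / sv
    is_filled <- function(a, b) {
      ok <- a >= 0 & a <= n & b >= 0 & b <= n
      out <- logical(length(a))
      out[ok] <- filled[cbind(a[ok] + 1, b[ok] + 1)]
      out
    }
    covered <- rep(FALSE, nrow(uv))
    ctol <- max(0.3, 2.5 / sv) # mask dilation is a pixel-scale effect
    for (da in c(-ctol, 0, ctol)) for (db in c(-ctol, 0, ctol))
      covered <- covered | is_filled(floor(ui + da), floor(vj + db))
    # confidence: per-cell margin from the decision boundary in units of
    # the read noise (estimated from the interior cells), squashed to
    # [0, 1]; a cell exactly at a boundary scores 0
    gap <- if (spec$scheme == "ternary") min(c_half, c_full - c_half) else c_full
    sigma_t <- max(stats::sd(t_model[i_int] - pred[i_int], na.rm = TRUE), 0.02)
    dist <- abs(t_model[i_arm] - pred[i_arm])
    conf <- mean(pmax(0, 2 * stats::pnorm((gap / 2 - dist) / sigma_t) - 1))
    list(m = m, sym = sym, resid = resid, cov = mean(covered),
         b = b_fit, conf = conf)
  }

  # polish origin from both starts; the target levels are the blur-
  # attenuated cell amplitudes, not the ideal 0/1 -- a heavily blurred
  # filled cell legitimately reads far below the align level
  sig0 <- sigma_of(s)
  att_full <- .predict_cell_means(list(c((1 - spec$fill_factor) / 2,
                                         (1 + spec$fill_factor) / 2,
                                         (1 - spec$fill_factor) / 2,
                                         (1 + spec$fill_factor) / 2)), sig0, self_cell)
  lv_att <- lv0 * att_full
  obj0 <- function(p) {
    m <- .sample_cells(img, p[1], p[2], s, th, cells)
    if (anyNA(m)) return(1)
    fg <- m[1]; bg <- stats::median(m[i_int])
    if (sign_fg * (fg - bg) < 0.04) return(1)
    t0 <- (m - bg) / (fg - bg) * att_full # align itself is attenuated
    darm <- vapply(t0[i_arm], function(x) min(abs(x - lv_att)), numeric(1))
    mean(c(abs(t0[1] - att_full), darm, pmax(t0[i_int], 0)))
  }
  opt <- stats::optim(o_img, obj0, method = "Nelder-Mead",
                      control = list(maxit = 80, reltol = 1e-6))
  opt2 <- stats::optim(o_img2, obj0, method = "Nelder-Mead",
                       control = list(maxit = 80, reltol = 1e-6))
  # judge raw and polished origins by how well the model read explains the
  # cluster, not by the polish objective -- the simplex can leave a good
  # basin when blur distorts the threshold-level objective
  quality <- function(r) if (is.null(r)) Inf else r$resid + 0.7 * (1 - r$cov)
  starts <- list(o_img, o_img2, opt$par, opt2$par)
  reads <- lapply(starts, function(q) read_model(q[1], q[2], s))
  qs <- vapply(reads, quality, numeric(1))
  if (all(!is.finite(qs))) return(dbg("read failed (NA samples or weak contrast)"))
  k_best <- which.min(qs)
  p <- starts[[k_best]]
  rm <- reads[[k_best]]
  if (rescue && (rm$resid > 0.14 || rm$cov < 0.8) &&
      rm$resid < 0.35 && rm$cov > 0.12) {
    # joint rescue: refit origin and pitch to explain both the intensities
    # and the mask pixels
    obj1 <- function(q) {
      if (q[3] < 0.85 * s0 || q[3] > 1.18 * s0) return(2)
      r2 <- read_model(q[1], q[2], q[3])
      if (is.null(r2)) return(2)
      r2$resid + 0.7 * (1 - r2$cov)
    }
    optr <- stats::optim(c(p, s), obj1, method = "Nelder-Mead",
                         control = list(maxit = 60, reltol = 1e-5))
    if (is.finite(optr$value) && optr$value < 1.9) {
      r2 <- read_model(optr$par[1], optr$par[2], optr$par[3])
      if (!is.null(r2) && (r2$resid + 0.7 * (1 - r2$cov) <
                           rm$resid + 0.7 * (1 - rm$cov))) {
        p <- optr$par[1:2]; s <- optr$par[3]; rm <- r2
      }
    }
  }
  if (rm$resid > 0.14) return(dbg(sprintf("model residual %.3f (s=%.2f)", rm$resid, s)))
  if (rm$cov < 0.8)
    return(dbg(sprintf("coverage %.2f (s=%.2f sym=%s resid=%.3f o=%.1f,%.1f)",
                       rm$cov, s, paste(rm$sym, collapse = ""), rm$resid, p[1], p[2])))
  sym <- rm$sym
  xs <- sym[1:n]; ys <- sym[(n + 1):(2 * n)]
  coord <- logical_decode(xs, ys, spec)
  # sub-pixel align corner: iterated intensity-weighted centroid of the
  # align cell, offset half a cell to the outer corner
  wing <- expand.grid(du = seq(-0.45, 0.45, length.out = 7),
                      dv = seq(-0.45, 0.45, length.out = 7))
  cen_u <- 0.5 * s; cen_v <- 0.5 * s
  for (it in 1:3) { # recentre: a clipped window under-corrects an offset
    dc <- .from_code_frame(cen_u + wing$du * s, cen_v + wing$dv * s, th)
    w <- sign_fg * (.bilinear(img, p[2] + dc[, 2], p[1] + dc[, 1]))
    w <- w - min(w, na.rm = TRUE); w[is.na(w)] <- 0
    if (sum(w) <= 0) break
    cen_u <- cen_u + sum(wing$du * w) / sum(w) * s
    cen_v <- cen_v + sum(wing$dv * w) / sum(w) * s
  }
  cor_d <- .from_code_frame(cen_u - 0.5 * s, cen_v - 0.5 * s, th)
  data.frame(x_index = coord[1], y_index = coord[2],
             px_row = p[2] + cor_d[1, 2], px_col = p[1] + cor_d[1, 1],
             orientation_deg = (th * 180 / pi) %% 360,
             confidence = rm$conf, feature_px = s,
             objective = rm$resid,
             ncc = .pattern_ncc(img, p[1] + cor_d[1, 1], p[2] + cor_d[1, 2],
                                s, th, spec, xs, ys, sign_fg))
}

#' Detect and decode grid codes in a grayscale image
#'
#' @param image numeric matrix `[row, col]` in \[0, 1\], or a PNG/TIFF path.
#' @param hints a [decode_hints()].
#' @param consistency apply [neighbor_consistency_filter()] to the
#'   detections (default `TRUE`).
#' @return data.frame with columns `x_index, y_index, px_row, px_col,
#'   orientation_deg, confidence` (one row per decoded code; sub-pixel
#'   position of the align-mark outer corner, 1-based pixel coordinates).
#'   Attributes: `feature_px` (estimated feature size in pixels),
#'   `polarity`, and `log` (messages about rejected candidates).
#' @export
detect_codes <- function(image, hints, consistency = TRUE) {
  if (is.character(image)) image <- read_image(image)
  if (!hints$spec$scheme %in% c("binary", "ternary"))
    stop("full-image detection supports the binary and ternary L-layouts; ",
         "use read_code_crop() for decimal/planet symbols")
  img <- (image - min(image)) / max(1e-12, diff(range(image)))
  pols <- if (hints$polarity == "auto") c("bright_features", "dark_features")
          else hints$polarity
  best <- NULL
  for (pol in pols) {
    det <- .detect_one_polarity(img, hints, pol)
    if (is.null(best) || nrow(det) > nrow(best) ||
        (nrow(det) == nrow(best) && nrow(det) > 0 &&
         mean(det$confidence) > mean(best$confidence))) best <- det
    # a decisive first polarity needs no counter-check
    if (nrow(best) >= 2 && mean(best$confidence) > 0.9) break
  }
  det <- best
  if (consistency && nrow(det) > 1)
    det <- neighbor_consistency_filter(det, hints)
  det
}

.empty_detections <- function(log = character(0), fpx = NA_real_, pol = NA_character_) {
  out <- data.frame(x_index = integer(0), y_index = integer(0),
                    px_row = numeric(0), px_col = numeric(0),
                    orientation_deg = numeric(0), confidence = numeric(0))
  attr(out, "log") <- log; attr(out, "feature_px") <- fpx
  attr(out, "polarity") <- pol
  out
}

.detect_one_polarity <- function(img, hints, pol) {
  spec <- hints$spec
  lg <- character(0)
  fpx_hint <- spec$feature_size / hints$approx_pixel_size
  # light denoising before thresholding only
  sm <- t(as.matrix(EBImage::gblur(t(img), sigma = max(0.8, 0.1 * fpx_hint))))
  # noise-adaptive threshold just above the background mode: blur
  # attenuates isolated single-cell bits far below the half-contrast level
  # where a class-balancing (Otsu) cut would land, so segment at the noise
  # floor instead and leave discrimination to despeckling and the lattice
  # model
  med <- stats::median(sm)
  sigma_n <- stats::mad(sm)
  q_ext <- if (pol == "bright_features") stats::quantile(sm, 0.999)
           else stats::quantile(sm, 0.001)
  # floor the threshold at a fraction of the apparent feature amplitude so
  # smooth low-noise scenes do not grow huge halos around every feature
  delta_thr <- max(4.5 * sigma_n, 0.15 * abs(q_ext - med))
  thr <- if (pol == "bright_features") med + delta_thr else med - delta_thr
  mask <- if (pol == "bright_features") sm > thr else sm < thr
  frac <- mean(mask)
  if (frac > 0.35) { # background is not the majority mode; fall back
    thr <- EBImage::otsu(EBImage::Image(t(sm)), range = c(0, 1))
    mask <- if (pol == "bright_features") sm > thr else sm < thr
    lg <- c(lg, sprintf(
      "noise-floor threshold selected %.0f%% of pixels; otsu fallback used",
      100 * frac))
  }
  sign_fg <- if (pol == "bright_features") 1 else -1
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask)))))
  nlab <- max(lab)
  if (nlab == 0) return(.empty_detections(c(lg, "no foreground components"), fpx_hint, pol))
  idx <- which(lab > 0)
  rows <- (idx - 1) %% nrow(lab) + 1
  cols <- (idx - 1) %/% nrow(lab) + 1
  labs <- lab[idx]
  area <- tabulate(labs, nlab)
  # despeckle: drop components far smaller than any plausible single cell
  min_area <- max(3, (0.3 * fpx_hint * 0.5)^2)
  keep <- which(area >= min_area)
  if (!length(keep)) return(.empty_detections(c(lg, "only speckle components"), fpx_hint, pol))
  # feature scale: blur-invariant flux/shape estimate from isolated
  # single-cell components, cross-checked against the hint; the component
  # areas serve as fallback
  flux <- .flux_feature_size(sm, med, sign_fg, rows, cols, labs, keep, fpx_hint)
  fpx_flux <- flux$f
  sigma_blur <- flux$sigma # pixels; NA when unknown
  if (is.finite(fpx_flux) && fpx_flux > 0.4 * fpx_hint && fpx_flux < 1.9 * fpx_hint) {
    fpx_est <- fpx_flux
    # the flux estimate can read up to ~25 percent low at extreme blur, so
    # the candidate band must reach well above it
    pitch_band <- c(0.7, 1.45)
  } else {
    small <- keep[area[keep] <= 2.25 * min(area[keep])]
    fpx_est <- sqrt(stats::median(area[small])) / spec$fill_factor
    if (!is.finite(fpx_est) || fpx_est < 0.45 * fpx_hint || fpx_est > 1.7 * fpx_hint) {
      lg <- c(lg, sprintf(
        "component-based scale estimate %.2f px/feature outside the trusted band of the hint %.2f; using the hint",
        fpx_est, fpx_hint))
      fpx_est <- fpx_hint
    }
    pitch_band <- c(0.6, 1.6)
  }
  sel <- labs %in% keep
  rows <- rows[sel]; cols <- cols[sel]; labs <- labs[sel]
  cen_r <- tapply(rows, labs, mean); cen_c <- tapply(cols, labs, mean)
  ids <- as.integer(names(cen_r))
  # group components into code candidates by single-linkage proximity
  lattice <- spec$symbols_per_axis + 1L
  if (length(ids) == 1L) {
    grp <- stats::setNames(1L, ids)
  } else {
    hc <- stats::hclust(stats::dist(cbind(cen_r, cen_c)), method = "single")
    grp <- stats::cutree(hc, h = (lattice + 1.3) * fpx_est)
    names(grp) <- ids
  }
  # collect the usable clusters
  clusters <- list()
  for (g in unique(grp)) {
    gl <- as.integer(names(grp)[grp == g])
    sel_g <- labs %in% gl
    pts <- cbind(rows[sel_g], cols[sel_g])
    cmp <- labs[sel_g]
    # a cluster near the frame border may belong to a truncated code whose
    # missing bits were clipped (and the faint cut remnant eroded by
    # thresholding); such fragments decode confidently to wrong
    # coordinates, so anything within about one cell of the border is not
    # attempted
    brd <- max(3, 1.1 * fpx_est)
    if (min(pts[, 1]) <= brd || min(pts[, 2]) <= brd ||
        max(pts[, 1]) > nrow(img) - brd || max(pts[, 2]) > ncol(img) - brd) {
      lg <- c(lg, sprintf("cluster at (%.0f, %.0f) reaches the frame border; skipped",
                          mean(pts[, 1]), mean(pts[, 2])))
      next
    }
    clusters[[length(clusters) + 1L]] <-
      list(pts = pts, cmp = cmp, a0 = .cluster_angles(pts, cmp))
  }
  if (!length(clusters)) return(.empty_detections(lg, fpx_est, pol))
  # every code in a scene shares one in-plane rotation; the circular mean
  # (mod 90 deg, by angle quadrupling) of the per-cluster estimates rescues
  # clusters whose own small/odd mask gives a poor angle
  if (length(clusters) >= 2) {
    z <- sum(exp(4i * unlist(lapply(clusters, function(cl) cl$a0[1]))))
    if (Mod(z) > 0) {
      scene_a <- (Arg(z) / 4) %% (pi / 2)
      for (k in seq_along(clusters)) {
        d <- abs(clusters[[k]]$a0 - scene_a)
        if (min(pmin(d, pi / 2 - d)) > 2 * pi / 180)
          clusters[[k]]$a0 <- c(clusters[[k]]$a0, scene_a)
      }
    }
  }
  if (isTRUE(getOption("gridcodes.debug2")))
    assign(".gc_debug", list(img = img, clusters = clusters, fpx_est = fpx_est,
                             sigma_blur = sigma_blur, sign_fg = sign_fg, pol = pol),
           envir = globalenv())
  # One pixel scale governs the whole scene, and a cluster holding only an
  # align mark plus one far bit is pitch-ambiguous on its own (a dilated
  # square 6 cells out also fits 5 cells of a 20 percent larger pitch), so
  # the pitch is estimated globally: sum the per-cluster lattice costs over
  # a shared candidate grid, letting structure-rich clusters pin the
  # minimum. Individual clusters then refine only within a narrow band.
  n_sym <- spec$symbols_per_axis
  lats <- lapply(clusters, function(cl) {
    uv <- .to_code_frame(cl$pts[, 2], cl$pts[, 1], cl$a0[1])
    .lattice_cost_fun(uv, cl$cmp, fpx_est, n_sym,
                      use_width = spec$scheme != "ternary")
  })
  lats <- lats[!vapply(lats, is.null, logical(1))]
  pitch_cands <- fpx_est
  if (length(lats)) {
    sgrid <- fpx_est * seq(pitch_band[1], pitch_band[2], by = 0.02)
    total <- vapply(sgrid, function(sc)
      sum(vapply(lats, function(lt) min(lt$cost(sc), 0.25), numeric(1))),
      numeric(1))
    # the lattice cost can tie between aliased pitches (an align mark plus
    # one far bit fits several); carry the few competitive, well-separated
    # minima forward and let the template match arbitrate
    ord <- order(total)
    cands <- numeric(0)
    for (i in ord) {
      if (!is.finite(total[i]) || total[i] > total[ord[1]] + 0.08) break
      if (!length(cands) || all(abs(sgrid[i] - cands) > 0.08 * sgrid[i]))
        cands <- c(cands, sgrid[i])
      if (length(cands) >= 3L) break
    }
    if (length(cands)) pitch_cands <- cands
    # the flux/shape estimate is the most robust absolute anchor: it leads
    # the candidate list, and mask-geometry candidates that nearly agree
    # with it are redundant
    if (is.finite(fpx_flux))
      pitch_cands <- c(fpx_flux,
                       pitch_cands[abs(pitch_cands - fpx_flux) > 0.05 * fpx_flux])
  }
  decode_all <- function(fpx, allow_rescue = FALSE) {
    dd <- list(); lgx <- character(0)
    for (cl in clusters) {
      cand <- list()
      for (a0 in cl$a0) {
        for (k in 0:3) {
          d <- .decode_candidate(img, cl$pts, cl$cmp, a0 + k * pi / 2,
                                 fpx, spec, sign_fg, sigma_px = sigma_blur)
          if (!is.null(d)) cand[[length(cand) + 1L]] <- d
        }
        # a confident decode with both arms non-empty is orientation-unique
        # (chiral L); further candidates cannot displace it
        if (length(cand) == 1L && cand[[1]]$x_index > 0 && cand[[1]]$y_index > 0 &&
            cand[[1]]$objective < 0.05 && cand[[1]]$confidence > 0.9) break
      }
      if (!length(cand) && allow_rescue) {
        # second pass with the joint origin/pitch rescue fit, only for
        # clusters where nothing decoded -- it is far more expensive, so
        # only the primary angle estimate is retried
        for (k in 0:3) {
          d <- .decode_candidate(img, cl$pts, cl$cmp, cl$a0[1] + k * pi / 2,
                                 fpx, spec, sign_fg, sigma_px = sigma_blur,
                                 rescue = TRUE)
          if (!is.null(d)) cand[[length(cand) + 1L]] <- d
        }
      }
      if (!length(cand)) {
        lgx <- c(lgx, sprintf("cluster at (%.0f, %.0f): no valid orientation",
                              mean(cl$pts[, 1]), mean(cl$pts[, 2])))
        next
      }
      dd[[length(dd) + 1L]] <- do.call(rbind, cand)
    }
    list(dets = dd, lg = lgx)
  }
  # decode under each candidate pitch; the pitch whose decodes best explain
  # the image wins. Two terms: the template cross-correlation of each
  # decode, and the agreement between inter-code pixel distances and the
  # distances their decoded indices imply at the known spacing (an aliased
  # pitch misreads indices by a factor, which this contradicts).
  # Spacing-consistency score per detection: each decoded pair implies a
  # ratio between its pixel distance and the distance its indices imply at
  # the known spacing; a correct detection has at least one partner with
  # ratio 1, a misread or aliased one does not. Ambiguous (multi-candidate,
  # often partial) clusters are excluded as unreliable.
  pitch_score <- function(dd, fp) {
    base <- sum(vapply(dd, function(cd) max(pmax(cd$ncc - 0.55, 0)), numeric(1)))
    uu <- Filter(function(cd) nrow(cd) == 1L, dd)
    if (length(uu) < 2) return(base)
    rows <- do.call(rbind, uu)
    cells_per_pitch <- spec$spacing / spec$feature_size
    pen <- vapply(seq_len(nrow(rows)), function(i) {
      best <- Inf
      for (j in seq_len(nrow(rows))) {
        if (j == i) next
        dk <- sqrt((rows$x_index[i] - rows$x_index[j])^2 +
                   (rows$y_index[i] - rows$y_index[j])^2)
        if (dk == 0) next
        dp <- sqrt((rows$px_row[i] - rows$px_row[j])^2 +
                   (rows$px_col[i] - rows$px_col[j])^2)
        best <- min(best, abs(log(dp / (dk * cells_per_pitch * fp))))
      }
      if (is.finite(best)) best else 0
    }, numeric(1))
    base - sum(pmin(2 * pen, 0.6))
  }
  best <- NULL; best_score <- -Inf
  for (fp in pitch_cands) {
    res <- decode_all(fp)
    sc <- if (length(res$dets)) pitch_score(res$dets, fp) else -1
    if (isTRUE(getOption("gridcodes.debug")))
      message(sprintf("pitch %.3f: %d clusters decoded, score %.3f",
                      fp, length(res$dets), sc))
    if (sc > best_score) { best_score <- sc; best <- res; fpx_est <- fp }
    # a pitch that decodes every cluster cleanly and consistently with the
    # known spacing needs no alternatives
    if (length(res$dets) == length(clusters) &&
        sc > 0.35 * length(clusters)) break
  }
  # second pass: the distance between detected anchors is an integer
  # multiple of the code spacing, giving a sub-pixel absolute pitch even
  # when the first-pass decode chose an aliased one (anchor corners stay
  # accurate under an alias); re-decode at that pitch if it scores better
  if (length(best$dets)) {
    # only clusters with a single valid orientation: an ambiguous cluster's
    # anchor can sit at the wrong lattice corner, across the code diagonal
    unamb_d <- Filter(function(cd) nrow(cd) == 1L, best$dets)
    rows <- do.call(rbind, unamb_d)
    if (!is.null(rows) && nrow(rows) >= 2) {
      dmat <- as.matrix(stats::dist(rows[, c("px_row", "px_col")]))
      d0 <- min(dmat[dmat > 0])
      cpp <- spec$spacing / spec$feature_size
      for (k in 1:3) {
        cand <- d0 / (k * cpp)
        if (abs(log(cand / fpx_est)) > log(1.5)) next
        if (abs(log(cand / fpx_est)) < 0.025) next
        res <- decode_all(cand)
        sc <- if (length(res$dets)) pitch_score(res$dets, cand) else -1
        if (isTRUE(getOption("gridcodes.debug")))
          message(sprintf("spacing-derived pitch %.3f: %d clusters, score %.3f",
                          cand, length(res$dets), sc))
        if (sc > best_score) { best_score <- sc; best <- res; fpx_est <- cand }
      }
    }
  }
  # a single cluster cannot pin the pitch through the code spacing, and its
  # own lattice cost has exact aliases at simple cell-count ratios; decode
  # at each alias of the chosen pitch and keep the best-explaining one
  if (length(clusters) == 1 && length(best$dets) == 1) {
    for (ratio in c(6 / 6.5, 5 / 6, 4 / 5, 6.5 / 6, 6 / 5, 5 / 4)) {
      fp2 <- fpx_est * ratio
      res2 <- decode_all(fp2)
      sc2 <- if (length(res2$dets)) pitch_score(res2$dets, fp2) else -1
      if (isTRUE(getOption("gridcodes.debug")))
        message(sprintf("alias pitch %.3f: score %.3f", fp2, sc2))
      if (sc2 > best_score) { best_score <- sc2; best <- res2; fpx_est <- fp2 }
    }
  }
  if (length(best$dets) < length(clusters)) {
    res <- decode_all(fpx_est, allow_rescue = TRUE)
    sc <- if (length(res$dets)) pitch_score(res$dets, fpx_est) else -1
    if (sc >= best_score) { best <- res; best_score <- sc }
  }
  dets <- best$dets
  lg <- c(lg, best$lg)
  if (!length(dets)) return(.empty_detections(lg, fpx_est, pol))
  # a best pitch whose detections barely correlate with their own templates
  # or contradict the known spacing explains nothing; report nothing
  if (length(dets) >= 2 && best_score < 0.05)
    return(.empty_detections(
      c(lg, "no pitch candidate explained the scene; detections withheld"),
      fpx_est, pol))
  # Codes with an all-zero arm admit more than one valid orientation (the
  # chiral-L argument needs both arms non-empty), so orientation is settled
  # by consensus across the unambiguous clusters of the scene; ambiguous
  # clusters with no consensus available are dropped, not guessed.
  circ_diff <- function(a, b) abs(((a - b + 180) %% 360) - 180)
  unamb <- vapply(dets, function(cd)
    length(unique(paste(cd$x_index, cd$y_index))) == 1L && nrow(cd) == 1L,
    logical(1))
  consensus <- NA_real_
  if (any(unamb)) {
    th <- vapply(dets[unamb], function(cd) cd$orientation_deg[which.max(cd$ncc)],
                 numeric(1)) * pi / 180
    consensus <- (atan2(sum(sin(th)), sum(cos(th))) * 180 / pi) %% 360
  }
  pick <- list()
  for (cd in dets) {
    if (nrow(cd) == 1L) { pick[[length(pick) + 1L]] <- cd; next }
    if (!is.na(consensus)) {
      dd <- circ_diff(cd$orientation_deg, consensus)
      near <- which(dd <= 30)
      if (length(near)) {
        cd <- cd[near, , drop = FALSE]
        pick[[length(pick) + 1L]] <- cd[which.max(cd$ncc), ]
        next
      }
    }
    if (length(unique(paste(cd$x_index, cd$y_index))) == 1L) {
      pick[[length(pick) + 1L]] <- cd[which.max(cd$ncc), ]
    } else {
      lg <- c(lg, sprintf(
        "cluster near (%.0f, %.0f): orientation-ambiguous decode with no scene consensus; dropped",
        cd$px_row[1], cd$px_col[1]))
    }
  }
  if (!length(pick)) return(.empty_detections(lg, fpx_est, pol))
  det <- do.call(rbind, pick)
  # duplicate coordinates: keep the higher confidence
  det <- det[order(-det$confidence), ]
  det <- det[!duplicated(det[, c("x_index", "y_index")]), ]
  # absolute spacing check: each detection should have a partner whose
  # pixel distance matches the index distance at the decoded pitch
  if (nrow(det) >= 2) {
    cpp <- spec$spacing / spec$feature_size
    pen <- vapply(seq_len(nrow(det)), function(i) {
      best_r <- Inf
      for (j in seq_len(nrow(det))) {
        if (j == i) next
        dk <- sqrt((det$x_index[i] - det$x_index[j])^2 +
                   (det$y_index[i] - det$y_index[j])^2)
        if (dk == 0) next
        dp <- sqrt((det$px_row[i] - det$px_row[j])^2 +
                   (det$px_col[i] - det$px_col[j])^2)
        best_r <- min(best_r, abs(log(dp / (dk * cpp * fpx_est))))
      }
      if (is.finite(best_r)) best_r else 0
    }, numeric(1))
    if (any(pen > 0.2)) {
      lg <- c(lg, sprintf("dropped %d detection(s) contradicting the grid spacing",
                          sum(pen > 0.2)))
      det <- det[pen <= 0.2, , drop = FALSE]
    }
    if (!nrow(det)) return(.empty_detections(lg, fpx_est, pol))
  }
  # a lone detection with an empty arm is rotation-ambiguous by
  # construction (the chirality argument needs both arms), and it is also
  # exactly what the visible corner of a mostly off-frame code decodes to;
  # without a corroborating neighbour it is withheld
  if (nrow(det) == 1 && (det$x_index[1] == 0 || det$y_index[1] == 0)) {
    lg <- c(lg, "solitary one-armed decode withheld: rotation-ambiguous without neighbours")
    return(.empty_detections(lg, fpx_est, pol))
  }
  # a solitary detection cannot corroborate its own pitch through the code
  # spacing, so it must stand on template quality alone: withhold it unless
  # its blurred-template correlation is decisive (aliased-pitch reads under
  # heavy blur score distinctly lower)
  if (nrow(det) == 1 &&
      (best_score < 0.3 ||
       (is.finite(sigma_blur) && sigma_blur > 0.35 * fpx_est))) {
    lg <- c(lg, sprintf(
      "solitary detection withheld: template score %.2f / blur %.2f cells cannot verify the pitch",
      best_score, if (is.finite(sigma_blur)) sigma_blur / fpx_est else NA))
    return(.empty_detections(lg, fpx_est, pol))
  }
  # a solitary detection could be the fragment of a larger code truncated
  # through empty cells, with our "align mark" really one of its bits; a
  # genuine code is confirmed by the extension strips behind the align
  # corner being visible inside the frame and empty
  if (nrow(det) == 1) {
    th1 <- det$orientation_deg[1] * pi / 180
    s1 <- det$feature_px[1]
    n1 <- spec$symbols_per_axis
    ext <- data.frame(i = c(-(1:n1) + 0.0, rep(0, n1), 0),
                      j = c(rep(0, n1), -(1:n1) + 0.0, 0)) # last row: align
    mx <- .sample_cells(img, det$px_col[1], det$px_row[1], s1, th1, ext)
    fg1 <- mx[2 * n1 + 1]
    bg1 <- stats::median(img)
    tx <- (mx[seq_len(2 * n1)] - bg1) / (fg1 - bg1)
    if (anyNA(tx) || any(tx > 0.45)) {
      lg <- c(lg, "solitary detection withheld: align-corner hinterland not verifiable in frame")
      return(.empty_detections(lg, fpx_est, pol))
    }
  }
  low <- det$confidence < hints$min_confidence
  if (any(low))
    lg <- c(lg, sprintf("dropped %d detection(s) below min_confidence", sum(low)))
  det <- det[!low, , drop = FALSE]
  fpx <- if (nrow(det)) stats::median(det$feature_px) else fpx_est
  det <- det[order(det$y_index, det$x_index),
             c("x_index", "y_index", "px_row", "px_col", "orientation_deg",
               "confidence")]
  rownames(det) <- NULL
  attr(det, "log") <- lg
  attr(det, "feature_px") <- fpx
  attr(det, "polarity") <- pol
  det
}

#' Filter detections to the largest lattice-consistent subset
#'
#' Navigating a grid presumes that decoded neighbours are geometrically
#' consistent: coordinate differences times the spacing must map to pixel
#' differences under one common similarity transform. This filter keeps the
#' largest subset of detections consistent with a single such transform
#' (tolerance 0.25 x spacing), removing corrupt decodes; singletons pass
#' unchanged.
#'
#' @param detections data.frame from [detect_codes()].
#' @param hints the [decode_hints()] used for detection.
#' @return the retained rows of `detections`.
#' @export
neighbor_consistency_filter <- function(detections, hints) {
  n <- nrow(detections)
  if (n < 2) return(detections)
  spacing <- hints$spec$spacing
  # grid physical coords (um, y up) and pixel coords in a y-up frame so the
  # common transform is a proper similarity
  P <- cbind(detections$x_index, detections$y_index) * spacing
  Q <- cbind(detections$px_col, -detections$px_row)
  zP <- complex(real = P[, 1], imaginary = P[, 2])
  zQ <- complex(real = Q[, 1], imaginary = Q[, 2])
  circ_diff <- function(a, b) abs(((a - b + 180) %% 360) - 180)
  best_in <- which.max(detections$confidence) # singleton fallback
  best_score <- -Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (zP[i] == zP[j]) next
    w <- (zQ[j] - zQ[i]) / (zP[j] - zP[i])
    if (Mod(w) == 0) next
    pred <- w * zP + (zQ[i] - w * zP[i])
    tol_px <- 0.25 * spacing * Mod(w)
    # the candidate transform must also agree with each detection's own
    # reported orientation (w acts in a y-up frame, hence the sign)
    th_w <- (-Arg(w)) * 180 / pi
    inl <- Mod(pred - zQ) <= tol_px &
      circ_diff(detections$orientation_deg, th_w) <= 20
    if (!any(inl)) next
    score <- sum(inl) + 1e-3 * sum(detections$confidence[inl])
    if (score > best_score) { best_score <- score; best_in <- which(inl) }
  }
  out <- detections[best_in, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("log", "feature_px", "polarity"))
    attr(out, a) <- attr(detections, a)
  out
}

#' Read the symbols of a single rectified code crop
#'
#' Decodes one code from an axis-aligned, upright crop whose extent equals
#' the code footprint -- the second rectification stage shared by all
#' schemes. For decimal codes each seven-segment subcell is sampled; for
#' planet codes bar heights are classified tall/short between the two
#' full-height frame bars. Binary/ternary crops are read on the cell
#' lattice.
#'
#' @param crop numeric matrix `[row, col]` covering exactly the code
#'   footprint, code y up = image up (row 1 is the top of the code).
#' @param spec a [grid_spec()].
#' @param polarity `"bright_features"` or `"dark_features"`.
#' @return integer vector `c(x_index, y_index)`.
#' @export
read_code_crop <- function(crop, spec,
                           polarity = c("bright_features", "dark_features")) {
  polarity <- match.arg(polarity)
  fp <- footprint(spec)
  n <- spec$symbols_per_axis
  sgn <- if (polarity == "bright_features") 1 else -1
  # mean intensity over the central half of a footprint-fraction box
  box <- function(x0, y0, x1, y1) { # code frame, um, y up
    mx <- (x0 + x1) / 2; my <- (y0 + y1) / 2
    w <- (x1 - x0) / 4; h <- (y1 - y0) / 4
    g <- expand.grid(x = seq(mx - w, mx + w, length.out = 3),
                     y = seq(my - h, my + h, length.out = 3))
    r <- (fp[2] - g$y) / fp[2] * (nrow(crop) - 1) + 1
    c_ <- g$x / fp[1] * (ncol(crop) - 1) + 1
    mean(.bilinear(crop, r, c_), na.rm = TRUE)
  }
  f <- spec$feature_size
  lvl <- function(v, fg, bg, levels) {
    t <- (v - bg) / (fg - bg)
    which.min(abs(t - levels)) - 1L
  }
  if (spec$scheme %in% c("binary", "ternary")) {
    cellv <- function(i, j) box(i * f, j * f, (i + 1) * f, (j + 1) * f)
    fg <- cellv(0, 0)
    bg <- stats::median(vapply(1:n, function(i) cellv(i, i), numeric(1)))
    levels <- if (spec$scheme == "ternary") c(0, 0.5, 1) else c(0, 1)
    xs <- vapply(1:n, function(k) lvl(cellv(k, 0), fg, bg, levels), integer(1))
    ys <- vapply(1:n, function(k) lvl(cellv(0, k), fg, bg, levels), integer(1))
  } else if (spec$scheme == "decimal") {
    fg <- box(0, 0, f, 11 * f) # align bar
    bg <- box(1.1 * f, 5.2 * f, 1.9 * f, 5.8 * f) # inter-row gap
    read_digit <- function(x_off, y_off) {
      m <- matrix(FALSE, 3, 5)
      for (ci in 1:3) for (rj in 1:5)
        m[ci, rj] <- lvl(box(x_off + (ci - 1) * f, y_off + (rj - 1) * f,
                             x_off + ci * f, y_off + rj * f), fg, bg, c(0, 1)) == 1L
      hit <- which(vapply(0:9, function(d) identical(.sevenseg_cells(d), m),
                          logical(1))) - 1L
      if (!length(hit)) stop("unrecognised seven-segment pattern")
      hit[1]
    }
    xs <- vapply(seq_len(n), function(k) read_digit((2 + 4 * (k - 1)) * f, 6 * f), numeric(1))
    ys <- vapply(seq_len(n), function(k) read_digit((2 + 4 * (k - 1)) * f, 0), numeric(1))
  } else { # planet
    nbar <- 2L + 10L * n
    fg <- box(0, 0, f, 2 * f) # frame bar base
    bg <- box(f, 3 * f, 2 * f, 5 * f) # gap above a short bar region
    tallness <- function(b) # 1 if the bar extends into the tall zone
      lvl(box(2 * b * f, 3 * f, (2 * b + 1) * f, 5 * f), fg, bg, c(0, 1))
    tall <- vapply(1:(nbar - 2L), function(b) tallness(b), integer(1))
    digit_of <- function(bits) {
      hit <- which(vapply(1:10, function(d) all(.planet_tall[d, ] == bits),
                          logical(1))) - 1L
      if (!length(hit)) stop("unrecognised two-of-five bar pattern")
      hit[1]
    }
    digs <- vapply(seq_len(2L * n), function(d)
      digit_of(tall[(5 * (d - 1) + 1):(5 * d)]), numeric(1))
    xs <- digs[1:n]; ys <- digs[(n + 1):(2 * n)]
  }
  logical_decode(xs, ys, spec)
}

#' Write detections to CSV
#' @param detections data.frame from [detect_codes()].
#' @param path output CSV.
#' @return invisibly, `path`.
#' @export
write_detections <- function(detections, path) {
  utils::write.csv(detections, path, row.names = FALSE)
  invisible(path)
}

#' Read detections from CSV
#' @param path CSV written by [write_detections()].
#' @return data.frame of detections.
#' @export
read_detections <- function(path) {
  utils::read.csv(path)
}
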