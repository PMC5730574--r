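# Altitude-resolved amplitude profiles and texture metrics. All profile
# angles are measured clockwise from the +x axis (a recording convention;
# peak counts are orientation-independent).

# Gaussian-smoothed continuous field of a mask plus physical axis coords.
# sigma = 1.5 voxels damps pixelation aliasing of the sub-pixel boundary to
# well below the 0.01 peak-prominence floor while preserving lobes with
# wavelengths of a few voxels or more.
mask_field <- function(mask, sigma = 1.5) {
  f <- gaussian_blur3d(array(as.numeric(mask), dim = dim(mask)), sigma)
  structure(f, voxel_size = voxel_size(mask), origin = attr(mask, "origin"))
}

# bilinear interpolation of a 2D matrix m (rows = y, cols = x) at continuous
# 1-based fractional indices (iy, ix); outside the grid returns 0
bilinear2d <- function(m, iy, ix) {
  ny <- nrow(m); nx <- ncol(m)
  out <- numeric(length(iy))
  ok <- iy >= 1 & iy <= ny & ix >= 1 & ix <= nx
  y0 <- pmin(floor(iy[ok]), ny - 1L); x0 <- pmin(floor(ix[ok]), nx - 1L)
  ty <- iy[ok] - y0; tx <- ix[ok] - x0
  v00 <- m[cbind(y0, x0)];     v01 <- m[cbind(y0, x0 + 1L)]
  v10 <- m[cbind(y0 + 1L, x0)]; v11 <- m[cbind(y0 + 1L, x0 + 1L)]
  out[ok] <- v00 * (1 - ty) * (1 - tx) + v01 * (1 - ty) * tx +
             v10 * ty * (1 - tx) + v11 * ty * tx
  out
}

#' Extract a sub-pixel cross-section contour at a given altitude
#'
#' The altitude fraction is measured down from the apex: the slice plane sits
#' at \eqn{z = z_{top} - f \cdot H} with `H` the nuclear thickness, so 0.25,
#' 0.50 and 0.75 are the top, middle and bottom altitudes. The contour is
#' obtained by casting rays from the slice centroid through a Gaussian-
#' smoothed intensity field and locating the 0.5 crossing with sub-pixel
#' interpolation.
#'
#' @param mask A `voxel_mask` at least 4 voxels thick.
#' @param altitude_fraction One of 0.25, 0.50, 0.75 (other values in (0, 1)
#'   require `override = TRUE`).
#' @param n_vertices Number of contour vertices (rays).
#' @param override Allow non-standard altitude fractions.
#' @return A `contour`: `n x 2` matrix of `(x, y)` vertices (um) with
#'   attributes `z`, `altitude` (top/middle/bottom), `center` and `radii`.
#' @export
slice_contour <- function(mask, altitude_fraction, n_vertices = 720L, override = FALSE) {
  check_mask(mask)
  std <- c(0.25, 0.5, 0.75)
  if (!isTRUE(override)) {
    check_that(any(abs(altitude_fraction - std) < 1e-9), "altitude_fraction",
               "must be 0.25, 0.50 or 0.75 (use override = TRUE for others)")
  } else {
    check_that(altitude_fraction > 0 && altitude_fraction < 1, "altitude_fraction",
               "must be in (0, 1)")
  }
  vs <- voxel_size(mask)
  zs_any <- which(apply(mask, 1, any))
  check_that(length(zs_any) >= 4, "mask", "must be at least 4 voxels thick")
  f <- mask_field(mask)
  co <- axis_coords(mask)
  z_top <- co$z[max(zs_any)]; z_bot <- co$z[min(zs_any)]
  z_star <- z_top - altitude_fraction * (z_top - z_bot)
  # interpolate field slice at z_star
  kz <- findInterval(z_star, co$z)
  kz <- min(max(kz, 1L), dim(f)[1] - 1L)
  tz <- (z_star - co$z[kz]) / (co$z[kz + 1] - co$z[kz])
  sl <- f[kz, , ] * (1 - tz) + f[kz + 1, , ] * tz
  inside <- sl >= 0.5
  if (!any(inside)) abort("empty slice at requested altitude", class = "nucmorph_no_object")
  # slice centroid (pixel centres of the inside region)
  w <- which(inside, arr.ind = TRUE)
  cy <- mean(co$y[w[, 1]]); cx <- mean(co$x[w[, 2]])
  label <- if (abs(altitude_fraction - 0.25) < 1e-9) "top"
           else if (abs(altitude_fraction - 0.5) < 1e-9) "middle"
           else if (abs(altitude_fraction - 0.75) < 1e-9) "bottom" else NA_character_
  theta <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  step <- min(vs["dx"], vs["dy"]) / 2
  rmax <- sqrt(diff(range(co$x))^2 + diff(range(co$y))^2)
  rr <- seq(0, rmax, by = step)
  radii <- numeric(n_vertices)
  for (i in seq_len(n_vertices)) {
    # clockwise from +x
    dxs <- cos(theta[i]); dys <- -sin(theta[i])
    px <- cx + rr * dxs; py <- cy + rr * dys
    ix <- (px - co$x[1]) / vs["dx"] + 1
    iy <- (py - co$y[1]) / vs["dy"] + 1
    vals <- bilinear2d(sl, iy, ix)
    s <- vals >= 0.5
    if (!s[1]) abort(sprintf("slice centroid not inside object (angle %.1f deg)",
                             rad2deg(theta[i])), class = "nucmorph_not_starshaped")
    down <- which(s[-length(s)] & !s[-1])
    if (length(down) != 1) {
      abort(sprintf("ray-boundary intersection not unique at angle %.1f deg (%d crossings); contour not star-shaped",
                    rad2deg(theta[i]), length(down)), class = "nucmorph_not_starshaped")
    }
    j <- down[1]
    radii[i] <- rr[j] + (0.5 - vals[j]) / (vals[j + 1] - vals[j]) * step
  }
  xy <- cbind(x = cx + radii * cos(theta), y = cy - radii * sin(theta))
  out <- new_contour(xy, z = z_star, altitude = label)
  attr(out, "center") <- c(x = cx, y = cy)
  attr(out, "radii") <- radii
  out
}

# polygon helpers -------------------------------------------------------------

polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

polygon_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(x = sum((x + xn) * cr) / (6 * a), y = sum((y + yn) * cr) / (6 * a))
}

# radius of a closed polygon from point `cen` along direction angle th
# (clockwise from +x); errors if the crossing is not unique
polygon_ray_radius <- function(xy, cen, th) {
  d <- c(cos(th), -sin(th))
  a <- xy
  b <- xy[c(2:nrow(xy), 1), , drop = FALSE]
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  # solve cen + t*d = a + u*e
  den <- d[1] * ey - d[2] * ex
  ok <- abs(den) > 1e-12
  t <- (( a[, 1] - cen[1]) * ey - (a[, 2] - cen[2]) * ex) / den
  u <- ((a[, 1] - cen[1]) * d[2] - (a[, 2] - cen[2]) * d[1]) / den
  hit <- ok & t > 1e-9 & u >= -1e-9 & u < 1 + 1e-9
  ts <- sort(t[hit])
  # a ray through a polygon vertex hits both incident segments; merge
  # crossings at (numerically) the same distance
  if (length(ts) > 1) ts <- ts[c(TRUE, diff(ts) > 1e-9 * max(ts))]
  if (length(ts) != 1) {
    abort(sprintf("ray-boundary intersection not unique at angle %.1f deg (%d crossings); contour not star-shaped",
                  rad2deg(th), length(ts)), class = "nucmorph_not_starshaped")
  }
  ts
}

#' Amplitude profile of a contour
#'
#' The centre-to-boundary distance as a function of angle (clockwise from
#' +x), normalized by the equivalent circular radius \eqn{r_{eq} =
#' \sqrt{A/\pi}} of the contour. For any star-shaped contour the mean of the
#' squared values is 1 (up to discretization), since \eqn{A = \frac12 \oint
#' r^2 d\theta}.
#'
#' @param contour A `contour` (from [slice_contour()] or
#'   [make_lobed_contour()]).
#' @param n_angles Number of uniform angular samples.
#' @return An `amplitude_profile` tibble with columns `angle` (degrees) and
#'   `value` (relative radius), carrying `r_eq`, `altitude`, `z` and
#'   `smoothed` attributes.
#' @export
amplitude_profile <- function(contour, n_angles = 360L) {
  check_that(inherits(contour, "contour"), "contour", "must be a contour")
  check_that(n_angles >= 16, "n_angles", "must be >= 16")
  radii_attr <- attr(contour, "radii")
  if (!is.null(radii_attr)) {
    r <- resample_circular(radii_attr, n_angles)
  } else {
    cen <- polygon_centroid(contour)
    th <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
    r <- vapply(th, function(t) polygon_ray_radius(contour, cen, t), numeric(1))
  }
  area <- polygon_area(contour)
  r_eq <- sqrt(area / pi)
  new_amplitude_profile(
    tibble::tibble(angle = 360 * (seq_len(n_angles) - 1) / n_angles,
                   value = r / r_eq),
    r_eq = r_eq, altitude = attr(contour, "altitude"), z = attr(contour, "z"),
    smoothed = FALSE)
}

new_amplitude_profile <- function(tbl, r_eq, altitude, z, smoothed) {
  structure(tbl, r_eq = r_eq, altitude = altitude, z = z, smoothed = smoothed,
            class = c("amplitude_profile", class(tibble::tibble())))
}

#' Savitzky-Golay smoothing of an amplitude profile
#'
#' Local least-squares polynomial smoothing of degree `poly_order` (default
#' 6) with circular (wrap-around) boundary handling, removing pixelation
#' noise while preserving genuine lobes.
#'
#' @param profile An `amplitude_profile`.
#' @param poly_order Polynomial degree (default 6).
#' @param window Odd window length, `> poly_order` (default 31 samples).
#' @return The smoothed `amplitude_profile`.
#' @export
smooth_profile <- function(profile, poly_order = 6L, window = 31L) {
  check_that(inherits(profile, "amplitude_profile"), "profile",
             "must be an amplitude_profile")
  check_that(window %% 2 == 1, "window", "must be odd")
  check_that(window > poly_order, "window", "must exceed poly_order")
  v <- profile$value
  n <- length(v)
  check_that(window <= n, "window", "must not exceed the profile length")
  pad <- c(v[(n - window + 1):n], v, v[1:window])
  sm <- signal::sgolayfilt(pad, p = poly_order, n = window)
  out <- profile
  out$value <- sm[(window + 1):(window + n)]
  attr(out, "smoothed") <- TRUE
  out
}

# circular local maxima with topographic prominence
circular_peaks <- function(v, min_prominence) {
  n <- length(v)
  if (n < 3 || diff(range(v)) == 0) return(integer(0))
  prv <- v[c(n, 1:(n - 1))]
  nxt <- v[c(2:n, 1)]
  cand <- which(v > prv & v >= nxt)
  keep <- logical(length(cand))
  gmin <- min(v)
  for (ci in seq_along(cand)) {
    p <- cand[ci]
    side_min <- function(dir) {
      m <- v[p]
      j <- p
      for (s in seq_len(n - 1)) {
        j <- ((j - 1 + dir) %% n) + 1
        if (v[j] > v[p]) return(m)
        m <- min(m, v[j])
      }
      NA_real_  # no higher ground: global maximum
    }
    l <- side_min(-1L); r <- side_min(1L)
    prom <- if (is.na(l) || is.na(r)) v[p] - gmin else v[p] - max(l, r)
    keep[ci] <- prom >= min_prominence
  }
  cand[keep]
}

#' Count peaks in a smoothed amplitude profile
#'
#' Circular local maxima with topographic prominence at least
#' `min_prominence` (relative-radius units). The default 0.01 suppresses
#' machine-precision ripples; a perfect circle has 0 peaks, a smooth ellipse
#' exactly 2 (at its major-axis tips).
#'
#' @param profile An `amplitude_profile` (ideally smoothed).
#' @param min_prominence Minimum peak prominence.
#' @return Integer peak count.
#' @export
count_peaks <- function(profile, min_prominence = 0.01) {
  check_that(inherits(profile, "amplitude_profile"), "profile",
             "must be an amplitude_profile")
  length(circular_peaks(profile$value, min_prominence))
}

#' Nuclear lateral bumpiness
#'
#' Runs slice -> amplitude profile -> Savitzky-Golay smoothing -> peak count
#' at the three standard altitudes (25, 50, 75% down from the apex) and
#' averages the three peak counts.
#'
#' @param mask A `voxel_mask`.
#' @param n_angles Angular samples per profile.
#' @param poly_order,window Savitzky-Golay parameters (see
#'   [smooth_profile()]).
#' @param min_prominence Peak prominence threshold (see [count_peaks()]).
#' @return One-row tibble: `peaks_top`, `peaks_middle`, `peaks_bottom`,
#'   `bumpiness` (their mean).
#' @export
lateral_bumpiness <- function(mask, n_angles = 360L, poly_order = 6L,
                              window = 31L, min_prominence = 0.01) {
  fractions <- c(top = 0.25, middle = 0.5, bottom = 0.75)
  peaks <- vapply(fractions, function(fr) {
    pr <- amplitude_profile(slice_contour(mask, fr), n_angles = n_angles)
    count_peaks(smooth_profile(pr, poly_order, window), min_prominence)
  }, numeric(1))
  tibble::tibble(peaks_top = peaks[["top"]], peaks_middle = peaks[["middle"]],
                 peaks_bottom = peaks[["bottom"]], bumpiness = mean(peaks))
}

#' Apical surface roughness
#'
#' Takes vertical cross-sections through the footprint centroid, extracts the
#' sub-voxel apical height profile h along the section, removes the smooth
#' baseline with a Savitzky-Golay filter (degree `poly_order`, window a
#' quarter of the profile length by default), and reports the residual height
#' variation normalized by the lateral extent of the scanned surface. The
#' variation statistic is RMS by default (`"sd"` and `"range"` selectable).
#'
#' @param mask A `voxel_mask`.
#' @param poly_order Savitzky-Golay degree for the baseline (default 6).
#' @param window Baseline window (odd); default: quarter of the profile
#'   length.
#' @param stat Height-variation statistic: `"rms"`, `"sd"` or `"range"`.
#' @param n_sections Number of azimuthally equispaced vertical sections to
#'   average over (default 1: the XZ plane through the centroid).
#' @return Dimensionless roughness (>= 0).
#' @export
surface_roughness <- function(mask, poly_order = 6L, window = NULL,
                              stat = c("rms", "sd", "range"), n_sections = 1L) {
  check_mask(mask)
  stat <- match.arg(stat)
  vs <- voxel_size(mask)
  f <- mask_field(mask)
  co <- axis_coords(mask)
  fp <- apply(mask, c(2, 3), any)
  w <- which(fp, arr.ind = TRUE)
  cy <- mean(co$y[w[, 1]]); cx <- mean(co$x[w[, 2]])
  nzd <- dim(f)[1]
  step <- min(vs["dx"], vs["dy"])
  half_len <- sqrt(diff(range(co$x))^2 + diff(range(co$y))^2) / 2
  tt <- seq(-half_len, half_len, by = step)
  one_section <- function(phi) {
    px <- cx + tt * cos(phi); py <- cy + tt * sin(phi)
    ix <- (px - co$x[1]) / vs["dx"] + 1
    iy <- (py - co$y[1]) / vs["dy"] + 1
    # column profiles: field along z at each sample point
    colv <- vapply(seq_len(nzd), function(k) bilinear2d(f[k, , ], iy, ix),
                   numeric(length(tt)))  # (samples x nz)
    h <- rep(NA_real_, length(tt))
    for (i in seq_along(tt)) {
      vzs <- colv[i, ]
      if (max(vzs) < 0.5) next
      topk <- max(which(vzs >= 0.5))
      if (topk == nzd) { h[i] <- co$z[nzd]; next }
      h[i] <- co$z[topk] + (0.5 - vzs[topk]) / (vzs[topk + 1] - vzs[topk]) *
        (co$z[topk + 1] - co$z[topk])
    }
    # contiguous run of the scanned surface containing the centre
    ok <- !is.na(h)
    mid <- which.min(abs(tt))
    if (!ok[mid]) abort("centroid column has no surface", class = "nucmorph_no_object")
    lo <- mid; while (lo > 1 && ok[lo - 1]) lo <- lo - 1
    hi <- mid; while (hi < length(tt) && ok[hi + 1]) hi <- hi + 1
    hs <- h[lo:hi]
    win <- window
    if (is.null(win)) {
      win <- round(length(hs) / 4)
      if (win %% 2 == 0) win <- win + 1
      win <- max(win, poly_order + 2 + (poly_order %% 2))
      if (win %% 2 == 0) win <- win + 1
    }
    if (length(hs) < win) {
      abort(sprintf("surface profile (%d samples) shorter than SG window (%d)",
                    length(hs), win), class = "nucmorph_validation_error")
    }
    baseline <- signal::sgolayfilt(hs, p = poly_order, n = win)
    resid <- hs - baseline
    extent <- tt[hi] - tt[lo]
    v <- switch(stat, rms = rms(resid), sd = sd(resid), range = diff(range(resid)))
    v / extent
  }
  phis <- pi * (seq_len(n_sections) - 1) / n_sections
  mean(vapply(phis, one_section, numeric(1)))
}

#' Combined texture metrics for one mask
#'
#' @inheritParams lateral_bumpiness
#' @param ... Passed to [surface_roughness()].
#' @return One-row tibble: the [lateral_bumpiness()] columns plus
#'   `roughness`.
#' @export
nuclear_texture <- function(mask, n_angles = 360L, poly_order = 6L,
                            window = 31L, min_prominence = 0.01, ...) {
  lb <- lateral_bumpiness(mask, n_angles, poly_order, window, min_prominence)
  lb$roughness <- surface_roughness(mask, poly_order = poly_order, ...)
  lb
}
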