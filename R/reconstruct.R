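new_voxel_mask <- function(mask, voxel_size, origin = NULL, threshold = NA_real_,
                           threshold_sensitivity = NA_real_) {
  storage.mode(mask) <- "logical"
  structure(mask,
            voxel_size = stats::setNames(as.numeric(voxel_size), c("dx", "dy", "dz")),
            origin = origin,
            threshold = threshold,
            threshold_sensitivity = threshold_sensitivity,
            class = c("voxel_mask", "array"))
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<voxel_mask> %d x %d x %d (z,y,x), %d foreground voxels, volume %.3g um^3\n",
              d[1], d[2], d[3], sum(x), measure_volume(x)))
  invisible(x)
}

check_mask <- function(mask) {
  check_that(inherits(mask, "voxel_mask"), "mask", "must be a voxel_mask")
  if (!any(mask)) abort("mask is empty", class = "nucmorph_empty_mask")
  invisible(TRUE)
}

# pooled-histogram Otsu threshold on raw intensity units
otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) abort("stack is constant; no object to segment",
                            class = "nucmorph_no_object")
  v <- (as.numeric(x) - rng[1]) / diff(rng)
  img <- EBImage::Image(matrix(v, ncol = 1))
  thr <- EBImage::otsu(img, range = c(0, 1), levels = 256L)
  rng[1] + thr * diff(rng)
}

# threshold -> largest component -> fill holes (no closing); shared by the
# main segmentation and the sensitivity probe
threshold_object <- function(stack, thr, min_voxels, do_close = FALSE) {
  fg <- array(stack >= thr, dim = dim(stack))
  if (!any(fg)) return(NULL)
  if (do_close) fg <- close3d(fg)
  comps <- label_components3d(fg)
  keep_sizes <- comps$sizes[comps$sizes >= min_voxels]
  if (!length(keep_sizes)) return(NULL)
  big <- which.max(comps$sizes)
  list(mask = fill_holes3d(comps$labels == big),
       sizes = sort(comps$sizes[comps$sizes >= min_voxels], decreasing = TRUE))
}

#' Segment the nucleus from a z-stack
#'
#' Automatic (Otsu) thresholding on the pooled intensity histogram, followed
#' by morphological closing (1-voxel radius, skipped for already-binary
#' input), retention of the largest 26-connected component above `min_size`,
#' and hole filling. The outer surface of the original imaging method is
#' asserted to be threshold-independent; here that claim is operationalized
#' as a reported threshold-sensitivity score: the maximal relative volume
#' change when the threshold is perturbed by +/-10%.
#'
#' @param stack An [image_stack()].
#' @param threshold `"otsu"` or an explicit numeric threshold in intensity
#'   units.
#' @param min_size Minimum object size in cubic micrometres; smaller
#'   components are discarded as debris.
#' @return A `voxel_mask` (logical array, `(z,y,x)`) carrying `voxel_size`,
#'   `origin`, `threshold` and `threshold_sensitivity` attributes.
#' @export
segment_nucleus <- function(stack, threshold = "otsu", min_size = 1) {
  check_that(inherits(stack, "image_stack"), "stack", "must be an image_stack")
  vs <- voxel_size(stack)
  min_voxels <- max(1, round(min_size / prod(vs)))
  if (diff(range(stack)) == 0) {
    abort("stack is constant; no object to segment", class = "nucmorph_no_object")
  }
  is_binary <- length(unique(as.numeric(stack))) <= 2
  thr <- if (identical(threshold, "otsu")) {
    if (is_binary) mean(range(stack)) else otsu_threshold(stack)
  } else {
    check_that(is.numeric(threshold), "threshold", "must be \"otsu\" or numeric")
    threshold
  }
  res <- threshold_object(stack, thr, min_voxels, do_close = !is_binary)
  if (is.null(res)) abort("no object found above threshold",
                          class = "nucmorph_no_object")
  if (length(res$sizes) > 1 && res$sizes[2] >= 0.5 * res$sizes[1]) {
    warn("multiple similar-size components; keeping the largest")
  }
  v0 <- sum(res$mask)
  sens <- vapply(c(0.9, 1.1), function(f) {
    r <- threshold_object(stack, thr * f, min_voxels, do_close = !is_binary)
    if (is.null(r)) return(1)
    abs(sum(r$mask) - v0) / v0
  }, numeric(1))
  new_voxel_mask(res$mask, vs, origin = attr(stack, "origin"),
                 threshold = thr, threshold_sensitivity = max(sens))
}

#' Nuclear volume
#'
#' Foreground voxel count times the voxel volume: the 3D domain of voxels
#' within the outer surface, integrated.
#'
#' @param mask A `voxel_mask`.
#' @return Volume in cubic micrometres.
#' @export
measure_volume <- function(mask) {
  check_mask(mask)
  sum(mask) * prod(voxel_size(mask))
}

#' Nuclear thickness
#'
#' Maximum basal-to-apical extent: for every (x, y) column the z extent of
#' the mask (top minus bottom plus one voxel), maximized over columns. For a
#' tilted nucleus this follows the object rather than its bounding box.
#'
#' @param mask A `voxel_mask`.
#' @return Thickness in micrometres.
#' @export
measure_thickness <- function(mask) {
  check_mask(mask)
  d <- dim(mask)
  top <- matrix(-Inf, d[2], d[3])
  bot <- matrix(Inf, d[2], d[3])
  for (k in seq_len(d[1])) {
    sl <- mask[k, , ]
    top[sl] <- k
    bot[sl] <- pmin(bot[sl], k)
  }
  ext <- top - bot + 1
  max(ext[is.finite(ext)]) * voxel_size(mask)["dz"]
}

# sub-pixel outline of a 2D binary footprint: light Gaussian smoothing, then
# the 0.5 contour line; returns list(xy matrix closed-implicitly, area, perimeter)
footprint_contour <- function(fp, dx, dy, sigma_px = 1) {
  arr <- array(as.numeric(fp), dim = c(1, dim(fp)))
  sm <- gaussian_blur3d(arr, c(0, sigma_px, sigma_px))[1, , ]
  xs <- (seq_len(ncol(fp)) - 1) * dx
  ys <- (seq_len(nrow(fp)) - 1) * dy
  cl <- grDevices::contourLines(x = xs, y = ys, z = t(sm), levels = 0.5)
  if (!length(cl)) abort("no footprint contour found", class = "nucmorph_no_object")
  shoelace <- function(p) {
    x <- p$x; y <- p$y
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }
  areas <- vapply(cl, shoelace, numeric(1))
  p <- cl[[which.max(areas)]]
  xy <- cbind(p$x, p$y)
  if (all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
  seg <- sqrt(rowSums((xy - xy[c(2:nrow(xy), 1), , drop = FALSE])^2))
  list(xy = xy, area = max(areas), perimeter = sum(seg))
}

#' Projected footprint area and shape factor
#'
#' The mask is projected onto the XY plane (a column is foreground if any of
#' its voxels is). Area is the footprint pixel count times the pixel area;
#' the shape factor is the circularity \eqn{4\pi A / P^2} of the sub-pixel
#' footprint outline (1 for a circle, lower for elongated or irregular
#' footprints; bounded by 1 via the isoperimetric inequality).
#'
#' @param mask A `voxel_mask`.
#' @return A tibble with columns `area` (um^2) and `shape_factor`.
#' @export
project_area_shape <- function(mask) {
  check_mask(mask)
  vs <- voxel_size(mask)
  fp <- apply(mask, c(2, 3), any)
  area <- sum(fp) * vs["dx"] * vs["dy"]
  fc <- footprint_contour(fp, vs["dx"], vs["dy"])
  sf <- 4 * pi * fc$area / fc$perimeter^2
  tibble::tibble(area = unname(area), shape_factor = unname(sf))
}

#' Full morphometry of one stack
#'
#' Segments the nucleus and reports the four morphometric quantities plus the
#' threshold-sensitivity score in one tibble row.
#'
#' @inheritParams segment_nucleus
#' @param ... Passed to [segment_nucleus()].
#' @return A one-row tibble: `volume` (um^3), `thickness` (um), `area`
#'   (um^2), `shape_factor`, `threshold_sensitivity`.
#' @export
morphometry <- function(stack, ...) {
  mask <- segment_nucleus(stack, ...)
  ps <- project_area_shape(mask)
  tibble::tibble(volume = measure_volume(mask),
                 thickness = unname(measure_thickness(mask)),
                 area = ps$area,
                 shape_factor = ps$shape_factor,
                 threshold_sensitivity = attr(mask, "threshold_sensitivity"))
}
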