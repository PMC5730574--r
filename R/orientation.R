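# Cell orientation: the angle between the longest chord through a binary
# cell mask and a reference (stretching) axis, folded into [0, 90] degrees so
# that a uniformly random population averages 45 degrees.

mask_points <- function(mask) {
  check_that(inherits(mask, "cell_mask") || (is.matrix(mask) && is.logical(mask)),
             "mask", "must be a cell_mask or logical matrix")
  if (!any(mask)) abort("mask is empty", class = "nucmorph_empty_mask")
  px <- attr(mask, "pixel_size")
  if (is.null(px)) px <- 1
  w <- which(mask, arr.ind = TRUE)
  cbind(x = (w[, 2] - 1) * px, y = (w[, 1] - 1) * px)
}

#' Longest chord through a cell mask
#'
#' The maximal pairwise distance between foreground pixel centres, computed
#' exactly on the convex hull (the hull diameter equals the brute-force
#' maximum over all boundary-point pairs).
#'
#' @param mask A `cell_mask` (or logical matrix with a `pixel_size`
#'   attribute).
#' @return List with `p1`, `p2` (chord endpoint coordinates, um) and
#'   `length` (um).
#' @export
longest_chord <- function(mask) {
  pts <- mask_points(mask)
  hull <- if (nrow(pts) >= 3) pts[grDevices::chull(pts), , drop = FALSE] else pts
  dd <- as.matrix(stats::dist(hull))
  ij <- which(dd == max(dd), arr.ind = TRUE)[1, ]
  list(p1 = hull[ij[1], ], p2 = hull[ij[2], ], length = max(dd), hull = hull)
}

#' Orientation angle of a cell mask
#'
#' Unsigned acute angle between the longest chord and a reference axis,
#' folded into `[0, 90]` degrees. Near-circular masks whose near-maximal
#' chords disagree in direction by more than 1 degree are flagged as
#' degenerate (the first maximal chord's angle is still returned).
#'
#' @param mask A `cell_mask`.
#' @param axis Reference axis as a 2-vector (default the x axis, the
#'   stretching direction).
#' @return One-row tibble: `angle` (degrees in `[0, 90]`), `chord_length`
#'   (um), chord endpoints, `degenerate` flag.
#' @export
orientation_angle <- function(mask, axis = c(1, 0)) {
  check_that(is.numeric(axis) && length(axis) == 2 && any(axis != 0),
             "axis", "must be a nonzero 2-vector")
  ch <- longest_chord(mask)
  v <- ch$p2 - ch$p1
  fold_angle <- function(v) {
    ct <- abs(sum(v * axis)) / (sqrt(sum(v^2)) * sqrt(sum(axis^2)))
    rad2deg(acos(pmin(pmax(ct, -1), 1)))
  }
  ang <- fold_angle(v)
  # degeneracy probe: chords within half a pixel of the maximum
  px <- attr(mask, "pixel_size"); if (is.null(px)) px <- 1
  hull <- ch$hull
  dd <- as.matrix(stats::dist(hull))
  near <- which(dd >= ch$length - px / 2 & dd > 0, arr.ind = TRUE)
  angs <- apply(near, 1, function(ij) fold_angle(hull[ij[2], ] - hull[ij[1], ]))
  degenerate <- (max(angs) - min(angs)) > 1
  tibble::tibble(angle = ang, chord_length = ch$length,
                 x1 = ch$p1[["x"]], y1 = ch$p1[["y"]],
                 x2 = ch$p2[["x"]], y2 = ch$p2[["y"]],
                 degenerate = degenerate)
}

#' Orientation of a population of masks
#'
#' @param masks List of `cell_mask` objects (e.g. from
#'   [sample_orientation_population()]).
#' @param axis Reference axis (see [orientation_angle()]).
#' @return Tibble with one row per mask.
#' @export
measure_orientation <- function(masks, axis = c(1, 0)) {
  check_that(is.list(masks) && length(masks) >= 1, "masks",
             "must be a non-empty list of cell masks")
  purrr::map_dfr(masks, orientation_angle, axis = axis)
}

#' Summarize a population of orientation angles
#'
#' @param results Tibble from [measure_orientation()] (needs an `angle`
#'   column), or a numeric vector of folded angles.
#' @return One-row tibble: `mean_angle`, `sem`, `n`.
#' @export
summarize_population <- function(results) {
  ang <- if (is.numeric(results)) results else results$angle
  check_that(!is.null(ang) && length(ang) >= 1, "results",
             "must contain at least one angle")
  n <- length(ang)
  tibble::tibble(mean_angle = mean(ang),
                 sem = if (n > 1) sd(ang) / sqrt(n) else 0,
                 n = n)
}
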