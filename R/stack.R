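#' Construct a 3D image stack
#'
#' Container for a confocal-style z-stack: a 3D intensity array in `(z, y, x)`
#' order together with the physical voxel size in micrometres. The z axis
#' increases apically, i.e. the basal side of the object is the lowest slice.
#'
#' @param intensities Numeric 3D array, dimensions `(nz, ny, nx)`. All values
#'   must be finite.
#' @param voxel_size Numeric length-3 vector `c(dx, dy, dz)` in micrometres
#'   (all positive).
#' @return An object of class `image_stack` (the array with a `voxel_size`
#'   attribute).
#' @export
image_stack <- function(intensities, voxel_size) {
  check_that(is.array(intensities) && length(dim(intensities)) == 3,
             "intensities", "must be a 3D array")
  check_that(all(dim(intensities) > 0), "intensities", "must be non-empty")
  check_that(all(is.finite(intensities)), "intensities", "must be finite")
  check_that(is.numeric(voxel_size) && length(voxel_size) == 3 && all(voxel_size > 0),
             "voxel_size", "must be 3 positive numbers (dx, dy, dz) in um")
  structure(intensities,
            voxel_size = stats::setNames(as.numeric(voxel_size), c("dx", "dy", "dz")),
            class = c("image_stack", "array"))
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  vs <- voxel_size(x)
  cat(sprintf("<image_stack> %d x %d x %d (z,y,x), voxel %.3g x %.3g x %.3g um\n",
              d[1], d[2], d[3], vs["dx"], vs["dy"], vs["dz"]))
  invisible(x)
}

#' Voxel size of a stack or mask
#'
#' @param x An `image_stack` or `voxel_mask`.
#' @return Named numeric vector `c(dx, dy, dz)` in micrometres.
#' @export
voxel_size <- function(x) attr(x, "voxel_size")

# physical coordinates (um) of voxel centres along each axis; the first voxel
# centre is at 0 unless an origin attribute says otherwise
axis_coords <- function(x) {
  d <- dim(x)
  vs <- voxel_size(x)
  org <- attr(x, "origin")
  if (is.null(org)) org <- c(0, 0, 0)  # (z0, y0, x0)
  list(z = org[1] + (seq_len(d[1]) - 1) * vs["dz"],
       y = org[2] + (seq_len(d[2]) - 1) * vs["dy"],
       x = org[3] + (seq_len(d[3]) - 1) * vs["dx"])
}

#' Write a stack as multi-page TIFF with a JSON sidecar
#'
#' Intensities are rescaled to `[0, 1]` for 32-bit float TIFF storage; the
#' original range and the voxel size are recorded in `<path>.json` so that
#' [read_stack()] restores the stack losslessly up to float precision.
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  vs <- voxel_size(stack)
  rng <- range(stack)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(dim(stack)[1]), function(k) (stack[k, , ] - rng[1]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- list(dx = unname(vs["dx"]), dy = unname(vs["dy"]), dz = unname(vs["dz"]),
                  intensity_min = rng[1], intensity_scale = scale,
                  axis_order = "zyx")
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' @param path TIFF path. If `<path>.json` exists it supplies the voxel size
#'   and intensity scaling; otherwise `voxel_size` must be given.
#' @param voxel_size Optional `c(dx, dy, dz)` in micrometres, overriding the
#'   sidecar.
#' @return An `image_stack`.
#' @export
read_stack <- function(path, voxel_size = NULL) {
  check_that(file.exists(path), "path", sprintf("file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path) else NULL
  if (is.null(voxel_size)) {
    check_that(!is.null(side), "voxel_size",
               "no sidecar JSON found; voxel_size must be supplied")
    voxel_size <- c(side$dx, side$dy, side$dz)
  }
  arr <- array(0, dim = c(length(pages), dim(pages[[1]])[1], dim(pages[[1]])[2]))
  for (k in seq_along(pages)) arr[k, , ] <- pages[[k]]
  if (!is.null(side) && !is.null(side$intensity_scale)) {
    arr <- arr * side$intensity_scale + side$intensity_min
  }
  image_stack(arr, voxel_size)
}
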