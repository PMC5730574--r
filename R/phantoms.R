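#' Specify a synthetic nucleus phantom
#'
#' Parametric family of star-shaped nuclear phantoms spanning the phenotypes of
#' interest: smooth ellipsoids (wild-type-like), laterally lobed ellipsoids
#' (lamin-deficient-like), vertically flattened nuclei (stretch response), and
#' apically rippled surfaces (surface wrinkling). The equatorial boundary
#' radius follows \eqn{r(\theta) = r_0(\theta)\,(1 + A\cos k\theta)} where
#' \eqn{r_0} is the base ellipse radius, `k = lobe_count` and
#' `A = lobe_amplitude`; the lobe modulation is applied uniformly in z.
#'
#' @param semi_axes `c(a, b, c)` ellipsoid semi-axes in micrometres.
#' @param lobe_count Integer `k >= 0`, number of cosine lobes.
#' @param lobe_amplitude Lobe amplitude as a fraction of radius, in `[0, 0.5)`.
#' @param flatten_factor Multiplier in `(0, 1]` applied to the vertical
#'   semi-axis `c` (1 = unflattened).
#' @param ripple `c(amplitude_um, wavelength_um)` apical surface ripple along
#'   x; `c(0, 0)` disables it.
#' @param noise_sd Gaussian intensity noise standard deviation (intensity
#'   units; object is ~0.9, background ~0.1).
#' @param voxel_size `c(dx, dy, dz)` voxel size in micrometres.
#' @param seed Integer RNG seed; stacks are bit-identical for identical
#'   spec + seed.
#' @param blur_sigma Optional isotropic Gaussian blur (um) applied to the
#'   noise-free object before noise, emulating mild optical blurring; 0
#'   disables it.
#' @return A `nucleus_phantom_spec` list.
#' @export
nucleus_phantom_spec <- function(semi_axes = c(8, 6, 3),
                                 lobe_count = 0L,
                                 lobe_amplitude = 0,
                                 flatten_factor = 1,
                                 ripple = c(0, 0),
                                 noise_sd = 0,
                                 voxel_size = c(0.2, 0.2, 0.2),
                                 seed = 1L,
                                 blur_sigma = 0) {
  check_that(is.numeric(semi_axes) && length(semi_axes) == 3 && all(semi_axes > 0),
             "semi_axes", "must be 3 positive lengths (a, b, c) in um")
  check_that(is.numeric(lobe_count) && length(lobe_count) == 1 &&
               lobe_count >= 0 && lobe_count == round(lobe_count),
             "lobe_count", "must be a non-negative integer")
  check_that(is.numeric(lobe_amplitude) && length(lobe_amplitude) == 1 &&
               lobe_amplitude >= 0 && lobe_amplitude < 1,
             "lobe_amplitude", "must be in [0, 1) so the radius stays positive")
  check_that(is.numeric(flatten_factor) && length(flatten_factor) == 1 &&
               flatten_factor > 0 && flatten_factor <= 1,
             "flatten_factor", "must be in (0, 1]")
  check_that(is.numeric(ripple) && length(ripple) == 2 && all(ripple >= 0),
             "ripple", "must be c(amplitude, wavelength) >= 0 in um")
  if (ripple[1] > 0) check_that(ripple[2] > 0, "ripple", "wavelength must be > 0")
  check_that(is.numeric(noise_sd) && length(noise_sd) == 1 && noise_sd >= 0,
             "noise_sd", "must be >= 0")
  check_that(is.numeric(voxel_size) && length(voxel_size) == 3 && all(voxel_size > 0),
             "voxel_size", "must be 3 positive numbers in um")
  check_that(is.numeric(seed) && length(seed) == 1, "seed", "must be a single integer")
  check_that(is.numeric(blur_sigma) && length(blur_sigma) == 1 && blur_sigma >= 0,
             "blur_sigma", "must be >= 0")
  structure(list(semi_axes = as.numeric(semi_axes),
                 lobe_count = as.integer(lobe_count),
                 lobe_amplitude = as.numeric(lobe_amplitude),
                 flatten_factor = as.numeric(flatten_factor),
                 ripple = as.numeric(ripple),
                 noise_sd = as.numeric(noise_sd),
                 voxel_size = as.numeric(voxel_size),
                 seed = as.integer(seed),
                 blur_sigma = as.numeric(blur_sigma)),
            class = "nucleus_phantom_spec")
}

# analytic inside test of the phantom at physical points centred on the
# nucleus; x, y, z equal-length vectors (um)
phantom_inside <- function(spec, x, y, z) {
  a <- spec$semi_axes[1]; b <- spec$semi_axes[2]
  cz <- spec$semi_axes[3] * spec$flatten_factor
  theta <- atan2(y, x)
  m <- 1 + spec$lobe_amplitude * cos(spec$lobe_count * theta)
  if (spec$ripple[1] > 0) {
    # apical ripple: perturb z increasingly toward the apex, zero below the
    # equator, so the basal side stays smooth
    zz <- z - spec$ripple[1] * cos(2 * pi * x / spec$ripple[2]) * pmax(z, 0) / cz
  } else {
    zz <- z
  }
  (x / (a * m))^2 + (y / (b * m))^2 + (zz / cz)^2 <= 1
}

#' Rasterize a nucleus phantom into an image stack
#'
#' Voxels with centres inside the analytic phantom get intensity 0.9,
#' background 0.1; optional Gaussian blur is applied, then Gaussian noise of
#' sd `noise_sd` is added (deterministically for a given seed). The stack is
#' padded by 3 background voxels on every side.
#'
#' @param spec A [nucleus_phantom_spec()].
#' @return An [image_stack()] with attributes `origin` (um position of the
#'   first voxel centre, `(z0, y0, x0)`) and `ground_truth_mask` (the
#'   noise-free rasterized object, a logical array).
#' @export
make_nucleus_stack <- function(spec) {
  check_that(inherits(spec, "nucleus_phantom_spec"), "spec",
             "must be created by nucleus_phantom_spec()")
  vs <- spec$voxel_size
  a <- spec$semi_axes[1]; b <- spec$semi_axes[2]
  cz <- spec$semi_axes[3] * spec$flatten_factor
  rmax_xy <- max(a, b) * (1 + spec$lobe_amplitude)
  pad <- 3
  xr <- rmax_xy + pad * vs[1]
  yr <- rmax_xy + pad * vs[2]
  zr <- cz + spec$ripple[1] + pad * vs[3]
  xs <- seq(-xr, xr, by = vs[1])
  ys <- seq(-yr, yr, by = vs[2])
  zs <- seq(-zr, zr, by = vs[3])
  nz <- length(zs); ny <- length(ys); nx <- length(xs)
  # evaluate slice by slice to bound memory
  mask <- array(FALSE, dim = c(nz, ny, nx))
  yg <- rep(ys, times = nx)
  xg <- rep(xs, each = ny)
  for (k in seq_len(nz)) {
    mask[k, , ] <- phantom_inside(spec, xg, yg, rep(zs[k], ny * nx))
  }
  img <- array(0.1, dim = dim(mask))
  img[mask] <- 0.9
  if (spec$blur_sigma > 0) {
    img <- gaussian_blur3d(img, spec$blur_sigma / vs[c(3, 2, 1)])
  }
  if (spec$noise_sd > 0) {
    img <- with_seed(spec$seed, img + array(rnorm(length(img), sd = spec$noise_sd),
                                            dim = dim(img)))
  }
  out <- image_stack(img, vs)
  attr(out, "origin") <- c(zs[1], ys[1], xs[1])
  attr(out, "ground_truth_mask") <- mask
  attr(out, "phantom_spec") <- spec
  out
}

#' Ground-truth voxel mask of a generated phantom
#'
#' @param stack A stack produced by [make_nucleus_stack()].
#' @return A `voxel_mask` (see [segment_nucleus()]) of the noise-free object.
#' @export
phantom_truth_mask <- function(stack) {
  m <- attr(stack, "ground_truth_mask")
  check_that(!is.null(m), "stack", "has no ground-truth mask attribute")
  new_voxel_mask(m, voxel_size(stack), origin = attr(stack, "origin"))
}

#' Closed lobed contour
#'
#' Samples the closed planar curve \eqn{r(\theta) = r_0 (1 + A\cos k\theta)}
#' at `n_samples` uniform angles. Used as a direct fixture for the texture
#' metrics.
#'
#' @param k Integer number of lobes (`k = 0` gives a circle).
#' @param amplitude Lobe amplitude fraction, `< 1`.
#' @param r0 Base radius (um).
#' @param n_samples Number of vertices (`>= 16`).
#' @return A `contour`: an `n x 2` matrix of `(x, y)` vertices (um) with the
#'   vertex angles as attribute.
#' @export
make_lobed_contour <- function(k, amplitude, r0 = 5, n_samples = 360L) {
  check_that(is.numeric(k) && length(k) == 1 && k >= 0 && k == round(k),
             "k", "must be a non-negative integer")
  check_that(is.numeric(amplitude) && amplitude >= 0 && amplitude < 1,
             "amplitude", "must be in [0, 1)")
  check_that(r0 > 0, "r0", "must be > 0")
  check_that(n_samples >= 16, "n_samples", "must be >= 16")
  theta <- 2 * pi * (seq_len(n_samples) - 1) / n_samples
  r <- r0 * (1 + amplitude * cos(k * theta))
  new_contour(cbind(x = r * cos(theta), y = r * sin(theta)),
              z = NA_real_, altitude = NA_character_)
}

new_contour <- function(xy, z, altitude) {
  structure(xy, class = c("contour", class(xy)), z = z, altitude = altitude)
}

#' Rasterize an elongated cell mask
#'
#' An ellipse of given aspect ratio whose major axis makes `angle` degrees
#' with the +x axis, rasterized at `pixel` micrometre resolution.
#'
#' @param angle Orientation of the major axis, degrees (any real; stored
#'   modulo 180).
#' @param aspect_ratio Major/minor axis ratio, `> 1` so the longest chord is
#'   unambiguous.
#' @param major_len Major axis length (um).
#' @param pixel Pixel size (um).
#' @return A `cell_mask`: logical matrix `(ny, nx)` with attributes
#'   `pixel_size` and `angle_true`.
#' @export
make_cell_mask <- function(angle, aspect_ratio = 3, major_len = 40, pixel = 0.5) {
  check_that(is.numeric(angle) && length(angle) == 1, "angle", "must be a number")
  check_that(is.numeric(aspect_ratio) && aspect_ratio > 1, "aspect_ratio",
             "must be > 1 (degenerate orientation otherwise)")
  check_that(major_len > 0, "major_len", "must be > 0")
  check_that(pixel > 0, "pixel", "must be > 0")
  A <- major_len / 2
  B <- A / aspect_ratio
  phi <- deg2rad(angle)
  half <- A + 2 * pixel
  xs <- seq(-half, half, by = pixel)
  ys <- xs
  xg <- rep(xs, each = length(ys))
  yg <- rep(ys, times = length(xs))
  # rotate into ellipse frame
  u <- cos(phi) * xg + sin(phi) * yg
  v <- -sin(phi) * xg + cos(phi) * yg
  inside <- (u / A)^2 + (v / B)^2 <= 1
  m <- matrix(inside, nrow = length(ys), ncol = length(xs))
  structure(m, class = c("cell_mask", "matrix"),
            pixel_size = pixel, angle_true = angle %% 180)
}

#' Generate a population of oriented cell masks
#'
#' @param n Number of cells (`>= 1`).
#' @param dist Orientation distribution: `"uniform"` (i.i.d. uniform on
#'   `[0, 180)` degrees), `"fixed"` (all at `angle`), or `"wrapped_normal"`
#'   (normal with mean `mu`, sd `sigma` degrees, wrapped into `[0, 180)`).
#' @param seed Integer seed; the population is deterministic given the seed.
#' @param angle Fixed angle (degrees) for `dist = "fixed"`.
#' @param mu,sigma Mean and sd (degrees) for `dist = "wrapped_normal"`.
#' @param aspect_ratio,major_len,pixel Passed to [make_cell_mask()].
#' @return List of `cell_mask` objects; the generating angles are attached as
#'   attribute `angles`.
#' @export
sample_orientation_population <- function(n, dist = c("uniform", "fixed", "wrapped_normal"),
                                          seed = 1L, angle = 0, mu = 90, sigma = 10,
                                          aspect_ratio = 3, major_len = 40, pixel = 0.5) {
  check_that(is.numeric(n) && length(n) == 1 && n >= 1 && n == round(n),
             "n", "must be a positive integer")
  dist <- match.arg(dist)
  angles <- with_seed(seed, switch(dist,
    uniform = runif(n, 0, 180),
    fixed = rep(angle, n),
    wrapped_normal = (rnorm(n, mu, sigma)) %% 180
  ))
  masks <- lapply(angles, make_cell_mask, aspect_ratio = aspect_ratio,
                  major_len = major_len, pixel = pixel)
  attr(masks, "angles") <- angles
  masks
}
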