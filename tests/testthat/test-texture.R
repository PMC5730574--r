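test_that("amplitude profiles are correctly normalized", {
  # circle: all values 1
  pr <- amplitude_profile(make_lobed_contour(0, 0, r0 = 4))
  expect_true(all(abs(pr$value - 1) < 0.01))
  # 2:1 ellipse: max relative radius = sqrt(2)
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  ell <- nucmorph:::new_contour(cbind(8 * cos(th), 4 * sin(th)), NA, NA)
  pre <- amplitude_profile(ell)
  expect_rel(max(pre$value), sqrt(2), 0.01)
  # normalization identity mean(value^2) = 1 for arbitrary star shapes
  for (k in c(0, 3, 6, 9)) {
    prk <- amplitude_profile(make_lobed_contour(k, 0.12, r0 = 5, n_samples = 720))
    expect_lt(abs(mean(prk$value^2) - 1), 0.01)
  }
})

test_that("non-star-shaped input is rejected with the offending angle", {
  # a C-shaped polygon (outer and inner arcs) is not star-shaped about its
  # centroid: rays toward the gap miss or multi-cross the boundary
  th1 <- seq(pi / 6, 11 * pi / 6, length.out = 120)
  xy <- rbind(cbind(5 * cos(th1), 5 * sin(th1)),
              cbind(3 * cos(rev(th1)), 3 * sin(rev(th1))))
  cres <- nucmorph:::new_contour(xy, NA, NA)
  expect_error(amplitude_profile(cres), "angle",
               class = "nucmorph_not_starshaped")
})

test_that("Savitzky-Golay smoothing preserves structure and damps noise", {
  pr <- amplitude_profile(make_lobed_contour(0, 0, r0 = 5))
  expect_equal(smooth_profile(pr)$value, pr$value, tolerance = 1e-9)
  # smooth lobed signal is passed through nearly unchanged
  pr5 <- amplitude_profile(make_lobed_contour(5, 0.1, r0 = 5, n_samples = 720))
  sm5 <- smooth_profile(pr5)
  expect_lt(max(abs(sm5$value - pr5$value)), 0.005)
  # white noise is attenuated (fixed seed)
  set.seed(11)
  noisy <- pr
  noise <- rnorm(nrow(pr), sd = 0.05)
  noisy$value <- pr$value + noise
  out <- smooth_profile(noisy)
  expect_lt(sd(out$value - pr$value), sd(noise))
  expect_error(smooth_profile(pr, poly_order = 6, window = 5), "window")
  expect_error(smooth_profile(pr, window = 30), "window")
})

test_that("peak counting matches construction", {
  expect_identical(count_peaks(smooth_profile(amplitude_profile(
    make_lobed_contour(0, 0, r0 = 5)))), 0L)
  # smooth ellipse: exactly two peaks
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  ell <- nucmorph:::new_contour(cbind(8 * cos(th), 5 * sin(th)), NA, NA)
  expect_identical(count_peaks(smooth_profile(amplitude_profile(ell))), 2L)
  expect_identical(count_peaks(smooth_profile(amplitude_profile(
    make_lobed_contour(5, 0.15, r0 = 5)))), 5L)
})

test_that("slice contours match analytic ellipsoid cross-sections", {
  m <- ellipsoid_mask()
  ct <- slice_contour(m, 0.5)
  pr <- amplitude_profile(ct)
  r_eq <- attr(pr, "r_eq")
  expect_rel(r_eq, sqrt(8 * 6), 0.02)   # mid-height section = full ellipse
  # top (25%) section is a smaller similar ellipse: z = c/2 -> scale sqrt(3)/2
  ct25 <- slice_contour(m, 0.25)
  expect_rel(attr(amplitude_profile(ct25), "r_eq"), sqrt(8 * 6 * 3 / 4), 0.03)
  ct75 <- slice_contour(m, 0.75)
  expect_rel(attr(amplitude_profile(ct75), "r_eq"), sqrt(8 * 6 * 3 / 4), 0.03)
  expect_error(slice_contour(m, 1.5), "altitude_fraction")
  expect_error(slice_contour(m, 0.4), "altitude_fraction")
  expect_s3_class(suppressWarnings(amplitude_profile(
    slice_contour(m, 0.4, override = TRUE))), "amplitude_profile")
})

test_that("lateral bumpiness recovers the generating lobe count", {
  expect_equal(lateral_bumpiness(ellipsoid_mask())$bumpiness, 2)
  expect_equal(lateral_bumpiness(lobed_mask())$bumpiness, 5)
  # sphere: constant radius at every altitude. Rasterization aliasing of a
  # circular boundary leaves a ~1% radial ripple even at 60 px radius, right
  # at the default prominence floor, so at most an occasional marginal peak
  # can survive; the bumpiness must sit far below the 2 of any true ellipse.
  ms <- segment_nucleus(make_nucleus_stack(
    nucleus_phantom_spec(semi_axes = c(3.02, 3.02, 3.02),
                         voxel_size = c(0.05, 0.05, 0.05))))
  expect_lte(lateral_bumpiness(ms)$bumpiness, 1)
})

test_that("bumpiness is invariant under in-plane rotation of the stack", {
  m <- lobed_mask()
  rot <- nucmorph:::new_voxel_mask(aperm(m[, , dim(m)[3]:1], c(1, 3, 2)),
                                   voxel_size(m)[c(2, 1, 3)])
  expect_equal(lateral_bumpiness(rot)$bumpiness,
               lateral_bumpiness(m)$bumpiness)
})

test_that("lobe count is recovered under noise across k (seeded replicates)", {
  cases <- expand.grid(k = c(3, 5, 8, 10), seed = c(1, 2))
  hits <- vapply(seq_len(nrow(cases)), function(i) {
    spec <- nucleus_phantom_spec(semi_axes = c(8, 6, 3),
                                 lobe_count = cases$k[i], lobe_amplitude = 0.12,
                                 noise_sd = 0.08, voxel_size = c(0.25, 0.25, 0.25),
                                 seed = cases$seed[i])
    m <- segment_nucleus(make_nucleus_stack(spec))
    lateral_bumpiness(m)$bumpiness == cases$k[i]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("surface roughness ranks ripple amplitude and is scale invariant", {
  smooth <- surface_roughness(ellipsoid_mask())
  expect_lt(smooth, 0.005)
  r1 <- surface_roughness(segment_nucleus(make_nucleus_stack(
    nucleus_phantom_spec(semi_axes = c(8, 6, 3), ripple = c(0.15, 2),
                         voxel_size = c(0.15, 0.15, 0.15)))))
  r2 <- surface_roughness(segment_nucleus(make_nucleus_stack(
    nucleus_phantom_spec(semi_axes = c(8, 6, 3), ripple = c(0.4, 2),
                         voxel_size = c(0.15, 0.15, 0.15)))))
  expect_gt(r1, smooth)
  expect_gt(r2, r1)
  # uniform x2 rescale leaves the normalized roughness unchanged (5%)
  ra <- surface_roughness(segment_nucleus(make_nucleus_stack(
    nucleus_phantom_spec(semi_axes = c(8, 6, 3), ripple = c(0.4, 2.5),
                         voxel_size = c(0.15, 0.15, 0.15)))))
  rb <- surface_roughness(segment_nucleus(make_nucleus_stack(
    nucleus_phantom_spec(semi_axes = 2 * c(8, 6, 3), ripple = c(0.8, 5),
                         voxel_size = c(0.3, 0.3, 0.3)))))
  expect_rel(rb, ra, 0.05)
})
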