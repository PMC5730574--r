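test_that("rasterized phantom volumes match closed forms", {
  # ellipsoid (8, 6, 3) um at 0.2 um voxels
  st <- make_nucleus_stack(nucleus_phantom_spec(semi_axes = c(8, 6, 3),
                                                voxel_size = c(0.2, 0.2, 0.2)))
  v <- measure_volume(phantom_truth_mask(st))
  expect_rel(v, 4 / 3 * pi * 8 * 6 * 3, 0.02)
  # 2 um sphere at 0.05 um voxels
  st2 <- make_nucleus_stack(nucleus_phantom_spec(semi_axes = c(1, 1, 1),
                                                 voxel_size = c(0.05, 0.05, 0.05)))
  expect_rel(measure_volume(phantom_truth_mask(st2)), 4 / 3 * pi, 0.02)
})

test_that("phantom volume converges to the analytic value as voxels shrink", {
  va <- 4 / 3 * pi * 4 * 3 * 2
  errs <- vapply(c(0.4, 0.2, 0.1), function(h) {
    st <- make_nucleus_stack(nucleus_phantom_spec(semi_axes = c(4, 3, 2),
                                                  voxel_size = rep(h, 3)))
    abs(measure_volume(phantom_truth_mask(st)) - va) / va
  }, numeric(1))
  expect_lt(errs[3], 0.02)            # voxel = min axis / 20
  expect_lt(errs[3], errs[1] + 1e-12) # finer is no worse
})

test_that("lobed contours carry exactly k radial maxima", {
  # k = 0: constant radius
  pr0 <- amplitude_profile(make_lobed_contour(0, 0, r0 = 5))
  expect_lt(diff(range(pr0$value)), 1e-6)
  # k = 2, maxima at 0 and 180 degrees
  pr2 <- amplitude_profile(make_lobed_contour(2, 0.1, r0 = 5), n_angles = 360)
  pk <- pr2$angle[pr2$value > max(pr2$value) - 1e-9]
  expect_true(all(round(pk) %in% c(0, 180)))
  for (k in c(3L, 5L, 7L, 9L, 12L)) {
    pr <- amplitude_profile(make_lobed_contour(k, 0.08, r0 = 5, n_samples = 720))
    expect_identical(count_peaks(smooth_profile(pr)), k)
  }
})

test_that("phantom generation is bit-identical for identical spec and seed", {
  spec <- nucleus_phantom_spec(semi_axes = c(4, 3, 2), noise_sd = 0.1,
                               voxel_size = c(0.25, 0.25, 0.25), seed = 42L)
  s1 <- make_nucleus_stack(spec)
  s2 <- make_nucleus_stack(spec)
  expect_identical(as.numeric(s1), as.numeric(s2))
  s3 <- make_nucleus_stack(nucleus_phantom_spec(semi_axes = c(4, 3, 2),
                                                noise_sd = 0.1,
                                                voxel_size = c(0.25, 0.25, 0.25),
                                                seed = 43L))
  expect_false(identical(as.numeric(s1), as.numeric(s3)))
})

test_that("phantom validation errors name the offending field", {
  expect_error(nucleus_phantom_spec(semi_axes = c(-1, 2, 3)), "semi_axes")
  expect_error(nucleus_phantom_spec(lobe_amplitude = 1.2), "lobe_amplitude")
  expect_error(nucleus_phantom_spec(voxel_size = c(0.2, 0, 0.2)), "voxel_size")
  expect_error(nucleus_phantom_spec(flatten_factor = 0), "flatten_factor")
  expect_error(make_lobed_contour(3, 1.5), "amplitude")
  expect_error(make_lobed_contour(3, 0.1, n_samples = 8), "n_samples")
  expect_error(make_cell_mask(30, aspect_ratio = 1), "aspect_ratio")
})

test_that("cell-mask orientation is recovered from generated masks", {
  expect_equal(orientation_angle(make_cell_mask(0))$angle, 0, tolerance = 1e-6)
  expect_equal(orientation_angle(make_cell_mask(90))$angle, 90, tolerance = 1e-6)
  # fold rule: 120 deg generates a 60 deg folded angle (rasterization leaves
  # a couple of degrees of farthest-pair quantization noise)
  expect_lt(abs(orientation_angle(make_cell_mask(120))$angle - 60), 3)
  expect_lt(abs(orientation_angle(make_cell_mask(30))$angle - 30), 3)
})

test_that("orientation populations are deterministic and follow their law", {
  pop <- sample_orientation_population(10, "fixed", angle = 60, seed = 1)
  ang <- measure_orientation(pop)$angle
  expect_true(all(abs(ang - 60) < 3))
  p1 <- sample_orientation_population(5, "uniform", seed = 9)
  p2 <- sample_orientation_population(5, "uniform", seed = 9)
  expect_identical(attr(p1, "angles"), attr(p2, "angles"))
  # wrapped-normal population centred at 90 folds to a mean above 45
  pw <- sample_orientation_population(60, "wrapped_normal", mu = 90, sigma = 10,
                                      seed = 3)
  expect_gt(summarize_population(measure_orientation(pw))$mean_angle, 55)
  expect_error(sample_orientation_population(0), "n")
})
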