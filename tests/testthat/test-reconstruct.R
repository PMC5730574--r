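test_that("segmentation recovers the generating mask on clean phantoms", {
  spec <- nucleus_phantom_spec(semi_axes = c(8, 6, 3), voxel_size = c(0.2, 0.2, 0.2))
  st <- make_nucleus_stack(spec)
  m <- segment_nucleus(st)
  gt <- phantom_truth_mask(st)
  dice <- 2 * sum(m & gt) / (sum(m) + sum(gt))
  expect_gte(dice, 0.99)
  # noisy phantom still segments well
  stn <- make_nucleus_stack(nucleus_phantom_spec(semi_axes = c(8, 6, 3),
                                                 noise_sd = 0.1,
                                                 voxel_size = c(0.2, 0.2, 0.2)))
  mn <- segment_nucleus(stn)
  dice_n <- 2 * sum(mn & gt) / (sum(mn) + sum(gt))
  expect_gte(dice_n, 0.97)
})

test_that("segmentation errors and degenerate inputs behave as specified", {
  bg <- image_stack(array(0.1, dim = c(8, 8, 8)), c(0.2, 0.2, 0.2))
  expect_error(segment_nucleus(bg), class = "nucmorph_no_object")
  # already-binary stack: idempotent (output equals input largest component)
  spec <- nucleus_phantom_spec(semi_axes = c(4, 3, 2), voxel_size = c(0.25, 0.25, 0.25))
  st <- make_nucleus_stack(spec)
  m <- segment_nucleus(st)
  expect_identical(which(as.logical(m)), which(attr(st, "ground_truth_mask")))
})

test_that("threshold sensitivity is negligible on noise-free phantoms", {
  m <- ellipsoid_mask()
  expect_lt(attr(m, "threshold_sensitivity"), 0.01)
})

test_that("volume, thickness and scaling behave like the closed forms", {
  one <- nucmorph:::new_voxel_mask(array(TRUE, c(1, 1, 1)), c(0.2, 0.2, 0.2))
  expect_equal(measure_volume(one), 0.008)
  expect_rel(measure_volume(sphere_mask()), 4 / 3 * pi, 0.02)
  expect_rel(measure_volume(ellipsoid_mask()), 603.19, 0.02)
  expect_lt(abs(measure_thickness(ellipsoid_mask()) - 6), 0.2 + 1e-9)
  # flattening scales thickness
  mf <- segment_nucleus(make_nucleus_stack(
    nucleus_phantom_spec(semi_axes = c(8, 6, 3), flatten_factor = 0.5,
                         voxel_size = c(0.2, 0.2, 0.2))))
  expect_lt(abs(measure_thickness(mf) - 3), 0.2 + 1e-9)
  # monotone scaling: s-scaled phantom has s^3 volume and s thickness
  m2 <- segment_nucleus(make_nucleus_stack(
    nucleus_phantom_spec(semi_axes = 1.5 * c(4, 3, 2), voxel_size = c(0.2, 0.2, 0.2))))
  m1 <- segment_nucleus(make_nucleus_stack(
    nucleus_phantom_spec(semi_axes = c(4, 3, 2), voxel_size = c(0.2, 0.2, 0.2))))
  expect_rel(measure_volume(m2) / measure_volume(m1), 1.5^3, 0.02)
  expect_lt(abs(measure_thickness(m2) / measure_thickness(m1) - 1.5), 0.15)
  expect_error(measure_volume(nucmorph:::new_voxel_mask(array(FALSE, c(2, 2, 2)),
                                                        c(1, 1, 1))),
               class = "nucmorph_empty_mask")
})

test_that("footprint area and shape factor match geometric references", {
  # flat disk, radius 5: circular footprint
  md <- segment_nucleus(make_nucleus_stack(
    nucleus_phantom_spec(semi_axes = c(5, 5, 1), voxel_size = c(0.1, 0.1, 0.1))))
  ps <- project_area_shape(md)
  expect_rel(ps$area, pi * 25, 0.02)
  expect_gt(ps$shape_factor, 0.97)
  expect_lte(ps$shape_factor, 1)
  # 8 x 4 um semi-axis ellipse footprint; Ramanujan perimeter reference
  me <- segment_nucleus(make_nucleus_stack(
    nucleus_phantom_spec(semi_axes = c(8, 4, 1), voxel_size = c(0.1, 0.1, 0.1))))
  pe <- project_area_shape(me)
  expect_rel(pe$area, pi * 32, 0.02)
  a <- 8; b <- 4
  per <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  expect_rel(pe$shape_factor, 4 * pi * (pi * a * b) / per^2, 0.03)
})

test_that("extracted surfaces are closed, genus 0, and metrically accurate", {
  mesh <- extract_surface(sphere_mask())
  expect_equal(mesh$euler_characteristic, 2)
  expect_rel(mesh_area(mesh), 4 * pi, 0.05)
  # two independent volume estimators agree
  expect_rel(mesh_volume(mesh), measure_volume(sphere_mask()), 0.02)
  mesh2 <- extract_surface(ellipsoid_mask())
  expect_equal(mesh2$euler_characteristic, 2)
  expect_rel(mesh_volume(mesh2), measure_volume(ellipsoid_mask()), 0.02)
})
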