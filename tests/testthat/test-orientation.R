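# brute-force farthest pair over all boundary pixels (the oracle the hull
# computation must reproduce)
brute_diameter <- function(mask) {
  px <- attr(mask, "pixel_size")
  inner <- mask
  inner[] <- FALSE
  inner[2:(nrow(mask) - 1), 2:(ncol(mask) - 1)] <-
    mask[1:(nrow(mask) - 2), 2:(ncol(mask) - 1)] &
    mask[3:nrow(mask), 2:(ncol(mask) - 1)] &
    mask[2:(nrow(mask) - 1), 1:(ncol(mask) - 2)] &
    mask[2:(nrow(mask) - 1), 3:ncol(mask)] &
    mask[2:(nrow(mask) - 1), 2:(ncol(mask) - 1)]
  w <- which(mask & !inner, arr.ind = TRUE)
  pts <- cbind((w[, 2] - 1) * px, (w[, 1] - 1) * px)
  max(stats::dist(pts))
}

test_that("longest chord equals closed forms on canonical shapes", {
  # ellipse, major axis 20 um
  ch <- longest_chord(make_cell_mask(0, aspect_ratio = 2.5, major_len = 20,
                                     pixel = 0.25))
  expect_lt(abs(ch$length - 20), 0.5)
  expect_lt(abs(abs(ch$p2[["x"]] - ch$p1[["x"]]) - 20), 0.5)
  # circle radius r: any diameter (build directly: low-eccentricity limit is
  # excluded by make_cell_mask, so rasterize a disk by hand)
  px <- 0.25
  xs <- seq(-6, 6, by = px)
  disk <- outer(xs, xs, function(y, x) x^2 + y^2 <= 25)
  attr(disk, "pixel_size") <- px
  class(disk) <- c("cell_mask", "matrix")
  expect_lt(abs(longest_chord(disk)$length - 10), 2 * px + 1e-9)
  # rectangle: diagonal
  rect <- matrix(FALSE, 41, 81)
  rect[6:36, 6:76] <- TRUE
  attr(rect, "pixel_size") <- 0.5
  class(rect) <- c("cell_mask", "matrix")
  L <- 70 * 0.5; W <- 30 * 0.5
  expect_lt(abs(longest_chord(rect)$length - sqrt(L^2 + W^2)), 0.5 + 1e-9)
})

test_that("hull-based chord equals the brute-force boundary oracle", {
  for (ang in c(10, 47, 101, 163)) {
    m <- make_cell_mask(ang, aspect_ratio = 2, major_len = 15, pixel = 0.5)
    expect_equal(longest_chord(m)$length, brute_diameter(m), tolerance = 1e-9)
  }
})

test_that("orientation folds into [0, 90] and is 180-degree periodic", {
  for (th in c(10, 40, 85, 110, 170)) {
    a1 <- orientation_angle(make_cell_mask(th))$angle
    a2 <- orientation_angle(make_cell_mask(th + 180))$angle
    expect_equal(a1, a2, tolerance = 1e-9)
    expect_gte(a1, 0); expect_lte(a1, 90)
  }
  # reference axis works for non-x axes too
  o <- orientation_angle(make_cell_mask(0), axis = c(0, 1))
  expect_equal(o$angle, 90, tolerance = 1e-6)
})

test_that("near-circular masks are flagged degenerate", {
  o <- orientation_angle(make_cell_mask(30, aspect_ratio = 1.02,
                                        major_len = 20, pixel = 0.25))
  expect_true(o$degenerate)
  o2 <- orientation_angle(make_cell_mask(30, aspect_ratio = 3))
  expect_false(o2$degenerate)
})

test_that("population summaries match closed forms", {
  s <- summarize_population(rep(60, 5))
  expect_equal(s$mean_angle, 60)
  expect_equal(s$sem, 0)
  # SEM uses the sample standard deviation: sd(30, 60) = 30/sqrt(2)
  s2 <- summarize_population(c(30, 60))
  expect_equal(s2$mean_angle, 45)
  expect_equal(s2$sem, sd(c(30, 60)) / sqrt(2), tolerance = 1e-9)
  expect_error(summarize_population(numeric(0)), "results")
})

test_that("uniformly oriented populations fold to a 45-degree mean", {
  # folding map alone, at large n
  set.seed(5)
  th <- runif(1e5, 0, 180)
  folded <- ifelse(th > 90, 180 - th, th)
  expect_lt(abs(mean(folded) - 45), 0.5)
  # measured through the full mask pipeline at moderate n
  pop <- sample_orientation_population(300, "uniform", seed = 21)
  s <- summarize_population(measure_orientation(pop))
  expect_lt(abs(s$mean_angle - 45), 3)
})
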