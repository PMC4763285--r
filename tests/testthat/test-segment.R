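test_that("equivalent diameter is the exact disk identity", {
  expect_equal(equivalent_diameter(pi * 10^2), 20)
  expect_equal(equivalent_diameter(pi / 4), 1)
  expect_equal(equivalent_diameter(100), 2 * sqrt(100 / pi))
  expect_equal(equivalent_diameter(100), 11.2838, tolerance = 1e-4)
  # exact for a sweep of radii
  r <- c(0.1, 1, 7, 33, 1000)
  expect_equal(equivalent_diameter(pi * r^2), 2 * r)
  expect_error(equivalent_diameter(0), "positive")
  expect_error(equivalent_diameter(-3), "positive")
})

test_that("background correction flattens illumination but keeps contrast", {
  flat <- hr_image(matrix(1, 120, 120), 1, 2.2)
  out <- correct_background(flat, 100)
  expect_equal(unclass(out)[, ], unclass(flat)[, ], tolerance = 1e-6)

  # known polynomial flat-field: residual ripple < 0.5%
  u <- seq(-1, 1, length.out = 120)
  ff <- 1 + 0.05 * outer(u, u, function(y, x) x + 0.5 * y - x^2)
  img <- hr_image(1000 * ff, 1, 2.2)
  corr <- correct_background(img, 100)
  expect_lt(diff(range(corr)) / mean(corr), 0.005)

  # colony contrast preserved within 5%
  s <- tiny_sensor()
  ph <- disk_phantom(s, 110, 110, diameter_um = 50)
  sc <- render_scene(ph, 0, supersample_S = 4)
  fr <- capture_frame(sc, c(0, 0), 80, 5, s,
                      noise_params(photon_budget = Inf, read_noise_sd = 0,
                                   flat_field_amplitude = 0.05))
  im <- hr_image(fr / 65535, 1, 2.2)
  corr2 <- correct_background(im, 200)
  depth_before <- 1 - min(im) / stats::median(im)
  depth_after <- 1 - min(corr2) / stats::median(corr2)
  expect_equal(depth_after, depth_before, tolerance = 0.05)
})

test_that("featureless noisy images segment to an empty region table", {
  set.seed(5)
  noise <- matrix(1 + rnorm(200 * 200, 0, 0.01), 200, 200)
  img <- hr_image(noise, 4, 0.55)
  regions <- segment_colonies(img)
  expect_equal(nrow(regions), 0)
  expect_equal(count_colonies(regions), 0L)
})

test_that("disjoint colonies are each found, sized, and thresholded correctly", {
  s <- sensor_spec(300, 300)
  xs <- c(100, 300, 500, 200, 450)
  ys <- c(100, 150, 100, 420, 480)
  ph <- disk_phantom(s, xs, ys, diameter_um = 30)
  sc <- render_scene(ph, 0, supersample_S = 4)
  fr <- capture_frame(sc, c(0, 0), 80, 5, s, noiseless())
  img <- hr_image(fr, 1, 2.2, focal_z_um = 5, timestamp_min = 0)
  regions <- segment_colonies(img)
  expect_equal(nrow(regions), 5)
  expect_true(all(regions$counted))
  expect_equal(regions$equivalent_diameter_um, rep(30, 5), tolerance = 2 * 2.2 / 30)
  # centroid recovery (x values are distinct; order by x to pair regions)
  ord <- order(regions$x_um)
  ord_true <- order(xs)
  expect_equal(regions$x_um[ord], xs[ord_true], tolerance = 0.1)
  expect_equal(regions$y_um[ord], ys[ord_true], tolerance = 0.1)

  # sub-threshold colonies are reported but not counted
  ph_small <- disk_phantom(s, xs[1:3], ys[1:3], diameter_um = 10)
  sc_s <- render_scene(ph_small, 0, supersample_S = 4)
  fr_s <- capture_frame(sc_s, c(0, 0), 80, 5, s, noiseless())
  reg_s <- segment_colonies(hr_image(fr_s, 1, 2.2))
  expect_equal(nrow(reg_s), 3)
  expect_false(any(reg_s$counted))
  expect_equal(count_colonies(reg_s), 0L)
})

test_that("raising the diameter cutoff never increases the count", {
  s <- sensor_spec(300, 300)
  ph <- disk_phantom(s, c(100, 300, 500, 200), c(100, 150, 100, 420),
                     diameter_um = 25)
  sc <- render_scene(ph, 0, supersample_S = 4)
  fr <- capture_frame(sc, c(0, 0), 80, 5, s, noiseless())
  img <- hr_image(fr, 1, 2.2)
  counts <- vapply(c(5, 15, 24, 26, 40), function(cut) {
    count_colonies(segment_colonies(img, segmentation_params(
      min_diameter_um = cut
    )))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], 4L)
  expect_equal(counts[5], 0L)
})

test_that("segmentation count matches the ground-truth merged-component count", {
  s <- sensor_spec(400, 400)
  set.seed(31)
  ph <- plate_phantom(s, n_colonies = 7, seed = 31, margin_um = 60,
                      growth = static_disks(35))
  sc <- render_scene(ph, 0, supersample_S = 4)
  fr <- capture_frame(sc, c(0, 0), 80, 5, s, noiseless())
  regions <- segment_colonies(hr_image(fr, 1, 2.2))
  gt <- phantom_ground_truth(ph, 0)
  expect_equal(nrow(regions), max(gt$merged_component_id))
})

test_that("border regions are flagged and excludable", {
  s <- sensor_spec(200, 200)
  ph <- disk_phantom(s, c(10, 220), c(220, 220), diameter_um = 40)
  sc <- render_scene(ph, 0, supersample_S = 4)
  fr <- capture_frame(sc, c(0, 0), 80, 5, s, noiseless())
  img <- hr_image(fr, 1, 2.2)
  reg <- segment_colonies(img)
  expect_equal(nrow(reg), 2)
  expect_equal(sum(reg$touches_border), 1)
  expect_equal(count_colonies(reg), 2L)
  reg_ex <- segment_colonies(img, segmentation_params(border_policy = "exclude"))
  expect_equal(count_colonies(reg_ex), 1L)
})
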