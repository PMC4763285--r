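test_that("degenerate shift-and-add is exact frame averaging", {
  zero <- tibble::tibble(dx = rep(0, 4), dy = rep(0, 4))
  frames <- lapply(1:4, function(k) matrix(k * 10, 6, 6))
  out <- shift_and_add(frames, zero, 1)
  expect_equal(unclass(out)[, ], matrix(25, 6, 6), ignore_attr = TRUE)
  set.seed(3)
  frames2 <- lapply(1:5, function(k) matrix(rpois(36, 100), 6, 6))
  out2 <- shift_and_add(frames2, tibble::tibble(dx = rep(0, 5), dy = rep(0, 5)), 1)
  expect_equal(unclass(out2)[, ], Reduce(`+`, frames2) / 5, ignore_attr = TRUE)
  expect_error(shift_and_add(list(matrix(NaN, 3, 3)),
                             tibble::tibble(dx = 0, dy = 0), 1), "NaN")
})

test_that("reconstruction conserves mean intensity and records focal depth", {
  s <- sensor_spec(80, 80)
  ph <- disk_phantom(s, 88, 88, diameter_um = 30, z_um = 50)
  sc <- render_scene(ph, 0, supersample_S = 8)
  sched <- design_scan(s, 50, 4, 8, 80)
  st <- capture_stack(sc, sched, 50, s)
  hr <- reconstruct_at(st, s, 50, 4)
  expect_equal(dim(hr), 4 * c(80, 80))
  expect_equal(attr(hr, "focal_z_um"), 50)
  expect_equal(attr(hr, "hr_pitch_um"), 2.2 / 4)
  lr_mean <- mean(vapply(st$frames, mean, numeric(1)))
  expect_equal(mean(hr), lr_mean, tolerance = 0.01)
})

test_that("Tenengrad sharpness has the required invariances", {
  const <- matrix(5, 32, 32)
  expect_equal(compute_sharpness(const), 0)
  set.seed(2)
  img <- matrix(runif(32 * 32), 32, 32)
  expect_equal(compute_sharpness(img + 100), compute_sharpness(img),
               tolerance = 1e-9)
  edge <- matrix(0, 64, 64); edge[, 33:64] <- 1
  blurred <- microcolony:::eb_gblur(edge, 3)
  expect_gt(compute_sharpness(edge), compute_sharpness(blurred))
  expect_error(compute_sharpness(img, roi = c(1, 40, 1, 10)), "roi")
})

test_that("reconstruction at the true depth is sharper than a defocused one", {
  s <- sensor_spec(64, 64)
  ztrue <- 60
  ph <- disk_phantom(s, 70, 70, diameter_um = 35, z_um = ztrue)
  sc <- render_scene(ph, 0, supersample_S = 8)
  sched <- design_scan(s, ztrue, 4, 8, 80)
  st <- capture_stack(sc, sched, ztrue, s)
  sharp_true <- compute_sharpness(reconstruct_at(st, s, ztrue, 4),
                                  presmooth_sigma_px = 1.5)
  sharp_zero <- compute_sharpness(reconstruct_at(st, s, 0, 4),
                                  presmooth_sigma_px = 1.5)
  sharp_off <- compute_sharpness(reconstruct_at(st, s, ztrue + 40, 4),
                                 presmooth_sigma_px = 1.5)
  expect_gt(sharp_true, sharp_zero)
  expect_gt(sharp_true, sharp_off)
})

test_that("autofocus recovers the sample plane and flags featureless scenes", {
  s <- sensor_spec(64, 64)
  ztrue <- 50
  ph <- disk_phantom(s, 70, 70, diameter_um = 35, z_um = ztrue)
  sc <- render_scene(ph, 0, supersample_S = 8)
  sched <- design_scan(s, ztrue, 4, 8, 80)
  st <- capture_stack(sc, sched, ztrue, s)
  af <- autofocus(st, s, seq(0, 100, 10), 4)
  expect_lte(abs(af$best_z_um - ztrue), 10)
  expect_s3_class(af$profile, "focus_profile")
  expect_equal(attr(af$profile, "best_z_um"), af$best_z_um)
  expect_error(autofocus(st, s, 50, 4), "at least two")

  # featureless scene: no depth preference, endpoint warning
  empty <- plate_phantom(s, n_colonies = 1, seed = 1, growth = growth_model())
  sc0 <- render_scene(empty, 0, supersample_S = 4)
  st0 <- capture_stack(sc0, sched, ztrue, s)
  expect_warning(autofocus(st0, s, seq(20, 80, 20), 4), "endpoint")
})

test_that("two-point pairs are resolved in HR but not in a single LR frame", {
  s <- sensor_spec(120, 120)
  mid <- 60 * 2.2; yy <- 59.5 * 2.2
  ph <- disk_phantom(s, c(mid - 2.2, mid + 2.2), c(yy, yy), diameter_um = 2)
  sc <- render_scene(ph, 0, supersample_S = 8, t_center = 0.05,
                     edge_width_um = 0.6)
  sched <- design_scan(s, 5, 4, 8, 80)
  set.seed(21)
  st <- capture_stack(sc, sched, 5, s, noise = noise_params())
  hr <- reconstruct_at(st, s, 5, 4)
  p1 <- c(mid - 2.2, yy); p2 <- c(mid + 2.2, yy)
  res_hr <- resolves_pair(hr, p1, p2)
  on_axis <- which.min(sched$source_x_mm^2 + sched$source_y_mm^2)
  res_lr <- resolves_pair(st$frames[[on_axis]], p1, p2, pitch_um = 2.2)
  expect_true(res_hr$resolved)
  expect_false(res_lr$resolved)
  expect_gt(res_hr$dip, res_lr$dip)
})
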