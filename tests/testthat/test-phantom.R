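test_that("growth law is linear after lag and non-decreasing", {
  expect_equal(colony_diameter(360, lag_min = 240, rate_um_min = 0.1), 25)
  expect_equal(colony_diameter(240, lag_min = 240, rate_um_min = 0.1), 1)
  expect_equal(colony_diameter(100, lag_min = 240, rate_um_min = 0.1), 1)
  d <- colony_diameter(seq(0, 720, 20), 240, 0.1)
  expect_true(all(diff(d) >= 0))
})

test_that("phantom seeding respects density, margins, separation, determinism", {
  s <- sensor_spec(500, 400)  # 1.1 x 0.88 mm
  ph <- plate_phantom(s, n_colonies = 12, seed = 4, margin_um = 100,
                      min_separation_um = 60)
  expect_equal(nrow(ph$colonies), 12)
  fov <- sensor_fov_um(s)
  expect_true(all(ph$colonies$x_um >= 100 & ph$colonies$x_um <= fov[1] - 100))
  dmat <- as.matrix(dist(ph$colonies[, c("x_um", "y_um")]))
  expect_true(all(dmat[upper.tri(dmat)] >= 60))
  expect_true(all(ph$colonies$rate_um_min > 0))
  ph2 <- plate_phantom(s, n_colonies = 12, seed = 4, margin_um = 100,
                       min_separation_um = 60)
  expect_identical(ph$colonies, ph2$colonies)
  # density-derived count: 80 CFU/cm^2 on this small chip rounds to 1
  ph3 <- plate_phantom(s, seed = 1)
  expect_gte(nrow(ph3$colonies), 1)
})

test_that("rendered scenes draw sigmoidal disks of the stated diameter", {
  s <- tiny_sensor()
  ph <- disk_phantom(s, 110, 110, diameter_um = 25)
  # nothing before the lag
  early <- render_scene(plate_phantom(s, n_colonies = 1, seed = 1,
                                      growth = growth_model()), 10)
  expect_true(all(early == 1))
  sc <- render_scene(ph, 0, supersample_S = 8)
  expect_true(all(sc >= 0 & sc <= 1))
  pitch_s <- attr(sc, "pitch_um")
  # area below the half-transmission level matches a 25-um disk
  half <- (1 + 0.35) / 2
  area_um2 <- sum(sc < half) * pitch_s^2
  expect_equal(2 * sqrt(area_um2 / pi), 25, tolerance = 0.05)
  # growth law plumbed through: d(360) = 1 + 2*0.1*120 = 25
  ph2 <- plate_phantom(s, n_colonies = 1, seed = 1,
                       growth = growth_model(mu_lag_min = 240, sd_lag_min = 0,
                                             mu_v_um_min = 0.1, sd_v_um_min = 0))
  ph2$colonies$x_um <- 110; ph2$colonies$y_um <- 110
  sc2 <- render_scene(ph2, 360, supersample_S = 8)
  area2 <- sum(sc2 < half) * attr(sc2, "pitch_um")^2
  expect_equal(2 * sqrt(area2 / pi), 25, tolerance = 0.05)
})

test_that("overlapping colonies merge into one connected dark component", {
  s <- tiny_sensor()
  ph <- disk_phantom(s, c(95, 125), c(110, 110), diameter_um = 40)
  sc <- render_scene(ph, 0, supersample_S = 4)
  lab <- microcolony:::eb_bwlabel(sc < 0.9)
  expect_equal(max(lab), 1)
  gt <- phantom_ground_truth(ph, 0)
  expect_equal(unique(gt$merged_component_id), 1)
  # merged-component count never exceeds the number of seeds
  set.seed(11)
  for (k in 1:5) {
    phk <- plate_phantom(sensor_spec(300, 300), n_colonies = 8, seed = k,
                         growth = static_disks(60))
    gtk <- phantom_ground_truth(phk, 0)
    expect_lte(max(gtk$merged_component_id), 8)
  }
})

test_that("noiseless capture integrates shadows onto the pixel grid", {
  s <- tiny_sensor()
  # empty scene at full illumination saturates to the full-scale value
  empty <- plate_phantom(s, n_colonies = 1, seed = 1, growth = growth_model())
  sc0 <- render_scene(empty, 0, supersample_S = 4)
  fr0 <- capture_frame(sc0, c(0, 0), 80, 5, s, noiseless())
  expect_true(all(fr0 == 65535L))
  # opaque 50-um disk: dark area ~ (pi/4) 50^2 / 2.2^2 ~ 405 LR px
  ph <- disk_phantom(s, 110, 110, diameter_um = 50)
  sc <- render_scene(ph, 0, supersample_S = 8, t_center = 0.0,
                     edge_width_um = 0.5)
  fr <- capture_frame(sc, c(0, 0), 80, 5, s, noiseless())
  dark <- sum(fr < 0.5 * 65535)
  expect_equal(dark, (pi / 4) * 50^2 / 2.2^2, tolerance = 0.1)
  # grid mismatch is an error
  expect_error(capture_frame(sc, c(0, 0), 80, 5, sensor_spec(50, 50), noiseless()),
               "does not match")
})

test_that("measured inter-frame displacement equals twice the single-source shift", {
  s <- tiny_sensor()
  ph <- disk_phantom(s, 110, 110, diameter_um = 30, z_um = 100)
  sc <- render_scene(ph, 0, supersample_S = 8)
  l <- c(8, 0)
  fa <- capture_frame(sc, l, 80, 100, s, noiseless(), blur_sigma_um_per_um = 0)
  fb <- capture_frame(sc, -l, 80, 100, s, noiseless(), blur_sigma_um_per_um = 0)
  # sub-pixel phase correlation oracle (FFT upsampled by zero-padding the
  # cross-power spectrum is overkill here: parabolic fit around the peak)
  xc <- function(a, b) {
    fa_ <- stats::fft(a); fb_ <- stats::fft(b)
    cp <- fa_ * Conj(fb_)
    r <- Re(stats::fft(cp / pmax(Mod(cp), 1e-12), inverse = TRUE))
    pk <- which(r == max(r), arr.ind = TRUE)[1, ]
    # parabolic sub-pixel refinement along x (columns)
    n <- ncol(a)
    cshift <- function(j) ((pk[2] - 1 + j) %% n) + 1
    y0 <- r[pk[1], cshift(-1)]; y1 <- r[pk[1], cshift(0)]; y2 <- r[pk[1], cshift(1)]
    frac <- 0.5 * (y0 - y2) / (y0 - 2 * y1 + y2)
    dx <- (pk[2] - 1 + frac)
    if (dx > n / 2) dx <- dx - n
    dx
  }
  measured_dx <- xc(fa, fb)
  expected <- 2 * compute_shadow_shift(l, 80, 100, s)["dx"]
  expect_equal(unname(measured_dx), unname(expected), tolerance = 0.05)
})

test_that("noiseless absorbed signal is invariant to the illumination shift", {
  s <- tiny_sensor()
  ph <- disk_phantom(s, 110, 110, diameter_um = 30, z_um = 50)
  sc <- render_scene(ph, 0, supersample_S = 8)
  absorbed <- function(l) {
    fr <- capture_frame(sc, l, 80, 50, s, noiseless(), blur_sigma_um_per_um = 0)
    sum(65535 - fr)
  }
  a0 <- absorbed(c(0, 0))
  a1 <- absorbed(c(10, 5))
  expect_equal(a1, a0, tolerance = 1e-3)
})

test_that("time-lapse simulation is deterministic and correctly enumerated", {
  s <- sensor_spec(60, 60)
  ph <- plate_phantom(s, n_colonies = 1, seed = 9,
                      growth = growth_model(sd_lag_min = 0, sd_v_um_min = 0))
  sched <- scan_schedule(c(0, 1), c(0, 0), 80)
  tl1 <- simulate_timelapse(ph, sched, 300, 300, 20, supersample_S = 4)
  expect_length(tl1$stacks, 1)
  tl2 <- simulate_timelapse(ph, sched, 0, 720, 20, supersample_S = 4,
                            noise = noiseless())
  expect_length(tl2$stacks, 37)
  expect_error(simulate_timelapse(ph, sched, 0, 100, 0), "positive")
  # byte-identical repeat runs under the same phantom seed
  a <- simulate_timelapse(ph, sched, 300, 340, 20, supersample_S = 4)
  b <- simulate_timelapse(ph, sched, 300, 340, 20, supersample_S = 4)
  expect_identical(a$stacks, b$stacks)
  expect_identical(a$ground_truth, b$ground_truth)
  # ground-truth trajectory non-decreasing per colony
  gt <- tl2$ground_truth
  for (id in unique(gt$colony_id)) {
    expect_true(all(diff(gt$true_diameter_um[gt$colony_id == id]) >= 0))
  }
})
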