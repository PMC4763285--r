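# build a minimal region table row
region_row <- function(t, label, x, y, d, counted = TRUE) {
  tibble::tibble(
    timepoint_min = t, label = label, x_um = x, y_um = y,
    area_um2 = pi * (d / 2)^2, equivalent_diameter_um = d, counted = counted
  )
}

test_that("a stationary colony yields a single track with one entry per frame", {
  regs <- dplyr::bind_rows(lapply(seq(0, 80, 20), function(t) {
    region_row(t, 1, 50, 50, 20 + t / 10)
  }))
  tr <- link_tracks(regs)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 5)
  expect_equal(attr(tr, "births")$birth_time_min, 0)
  expect_equal(nrow(attr(tr, "merges")), 0)
})

test_that("late-appearing colonies get their birth time", {
  regs <- dplyr::bind_rows(
    region_row(200, 1, 50, 50, 22),
    region_row(240, 1, 50, 50, 25),
    region_row(240, 2, 150, 80, 20),
    region_row(280, 1, 50, 50, 28),
    region_row(280, 2, 150, 80, 24)
  )
  tr <- link_tracks(regs)
  births <- attr(tr, "births")
  expect_equal(nrow(births), 2)
  expect_equal(sort(births$birth_time_min), c(200, 240))
})

test_that("duplicate labels within a timepoint are rejected", {
  regs <- dplyr::bind_rows(region_row(0, 1, 10, 10, 20),
                           region_row(0, 1, 40, 40, 20))
  expect_error(link_tracks(regs), "duplicate")
})

test_that("converging colonies merge, the larger parent survives", {
  # two colonies approach until only one (merged) region remains at t=80
  regs <- dplyr::bind_rows(
    region_row(0, 1, 50, 50, 30), region_row(0, 2, 90, 50, 20),
    region_row(20, 1, 52, 50, 32), region_row(20, 2, 88, 50, 22),
    region_row(40, 1, 54, 50, 34), region_row(40, 2, 86, 50, 24),
    region_row(60, 1, 65, 50, 48)
  )
  tr <- link_tracks(regs, max_link_distance_um = 25)
  merges <- attr(tr, "merges")
  expect_equal(nrow(merges), 1)
  expect_equal(merges$merge_time_min, 60)
  # the smaller track (id 2) merges into the larger (id 1)
  expect_equal(merges$track_id, 2)
  expect_equal(merges$merged_into, 1)
  # post-merge exactly one live track
  expect_equal(sum(tr$timepoint_min == 60), 1)
  expect_equal(tr$track_id[tr$timepoint_min == 60], 1)
})

test_that("track bookkeeping conserves births across merges", {
  # births = active + cumulative merges at every timepoint (noiseless case:
  # tracks never vanish except by merging)
  set.seed(12)
  s <- sensor_spec(400, 400)
  ph <- plate_phantom(s, n_colonies = 6, seed = 12, margin_um = 80,
                      growth = growth_model(mu_lag_min = 60, sd_lag_min = 30,
                                            mu_v_um_min = 0.3, sd_v_um_min = 0.05))
  times <- seq(60, 300, 40)
  regs <- dplyr::bind_rows(lapply(times, function(t) {
    sc <- render_scene(ph, t, supersample_S = 4)
    fr <- capture_frame(sc, c(0, 0), 80, 5, s, noiseless())
    r <- segment_colonies(hr_image(fr, 1, 2.2, timestamp_min = t),
                          segmentation_params(min_diameter_um = 5))
    r
  }))
  # gate wide enough that a merged region stays linkable to both parents
  # despite the centroid jump at the merge frame
  tr <- link_tracks(regs, max_link_distance_um = 40)
  births <- attr(tr, "births")
  merges <- attr(tr, "merges")
  for (t in times) {
    active <- length(unique(tr$track_id[tr$timepoint_min == t]))
    merged_so_far <- sum(merges$merge_time_min <= t)
    born_so_far <- sum(births$birth_time_min <= t)
    expect_equal(active + merged_so_far, born_so_far)
  }
  # diameters non-decreasing along unmerged noiseless tracks
  for (id in setdiff(unique(tr$track_id), merges$merged_into)) {
    d <- tr$equivalent_diameter_um[tr$track_id == id]
    if (length(d) > 1) expect_true(all(diff(d) > -0.5))
  }
})

test_that("size distribution uses the sample SD with n-1 and flags degenerate n", {
  regs <- dplyr::bind_rows(
    region_row(100, 1, 10, 10, 20), region_row(100, 2, 50, 50, 30),
    region_row(100, 3, 90, 90, 40), region_row(140, 1, 10, 10, 30)
  )
  tr <- link_tracks(regs, max_link_distance_um = 5)
  sd1 <- size_distribution(tr, 100)
  expect_equal(sd1$mean_diameter_um, 30)
  expect_equal(sd1$sd_diameter_um, 10)
  expect_equal(sd1$n, 3)
  expect_equal(sd1$flag, "ok")
  sd2 <- size_distribution(tr, 140)
  expect_equal(sd2$sd_diameter_um, 0)
  expect_equal(sd2$flag, "n=1")
  sd3 <- size_distribution(tr, 999)
  expect_equal(sd3$flag, "empty")
  expect_true(is.na(sd3$mean_diameter_um))
})

test_that("saturation time follows the 95%-of-final definition", {
  expect_equal(saturation_time(c(0, 0, 10, 48, 50, 50),
                               c(0, 120, 240, 360, 480, 600)), 360)
  expect_equal(saturation_time(c(7, 7, 7), c(0, 20, 40)), 0)
  expect_equal(saturation_time(c(1, 2, 3, 4), c(0, 20, 40, 60)), 60)
  expect_warning(out <- saturation_time(c(0, 0), c(0, 20)), "zero")
  expect_true(is.na(out))
})

test_that("titer arithmetic and input validation", {
  expect_equal(estimate_titer(50, 1, 1), 5e4)
  expect_equal(estimate_titer(50, 1, 100), 5e6)
  expect_equal(estimate_titer(0, 2, 10), 0)
  expect_error(estimate_titer(50, 0), "positive")
  expect_error(estimate_titer(50, 1, 0.5), ">= 1")
  expect_error(estimate_titer(-1, 1), "non-negative")
})

test_that("density bound scales exactly with inverse footprint area", {
  expect_equal(density_scale_bound(10, 1000, 1000), 10)
  expect_equal(density_scale_bound(10, 1000, 20), 25000)
  expect_equal(density_scale_bound(10, 1000, 500), 40)
  # exactly quadratic in the ratio
  base <- 10
  ratios <- c(0.5, 1, 2, 5, 50)
  got <- vapply(ratios, function(r) density_scale_bound(base, 1000, 1000 / r),
                numeric(1))
  expect_equal(got, base * ratios^2)
  expect_error(density_scale_bound(10, 0, 20), "positive")
})

test_that("timeseries report aggregates counts, saturation, density and titer", {
  regs <- dplyr::bind_rows(
    region_row(0, 1, 50, 50, 10, counted = FALSE),
    region_row(20, 1, 50, 50, 22),
    region_row(40, 1, 50, 50, 25),
    region_row(40, 2, 150, 150, 21),
    region_row(60, 1, 50, 50, 28),
    region_row(60, 2, 150, 150, 24)
  )
  s <- sensor_spec(200, 200)  # 0.44 x 0.44 mm
  rep <- timeseries_report(regs, s, sample_volume_ul = 1, dilution_factor = 10)
  expect_equal(rep$per_timepoint$count, c(0, 1, 2, 2))
  expect_equal(rep$final_count, 2)
  expect_equal(rep$saturation_time_min, 40)
  expect_equal(rep$density_cfu_cm2, 2 / (0.044^2))
  expect_equal(rep$titer_cfu_ml, 2 * 10 / 1e-3)
  g <- glance(rep)
  expect_equal(g$final_count, 2)
  td <- tidy(rep)
  expect_equal(nrow(td), 4)
})
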