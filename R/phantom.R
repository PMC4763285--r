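#' Colony growth model
#'
#' Per-colony growth parameters for the phantom generator. Each colony is a
#' disk whose diameter follows linear radial expansion after a lag:
#' `d(t) = d0 + 2 * v * max(0, t - t0)`. Lag times are Normal(mu_lag,
#' sd_lag); radial rates are Normal(mu_v, sd_v) truncated positive. The
#' defaults (lag 240 +/- 40 min, rate 0.10 +/- 0.02 um/min, seed diameter
#' 1 um) emulate an early-stage *S. epidermidis* microcolony culture whose
#' mean equivalent diameter passes ~24 um near 6 h of incubation and keeps
#' increasing monotonically thereafter.
#'
#' @param mu_lag_min,sd_lag_min Mean and SD of the per-colony lag time, min.
#' @param mu_v_um_min,sd_v_um_min Mean and SD of the radial growth rate,
#'   um/min (draws are truncated strictly positive).
#' @param seed_diameter_um Diameter at the end of lag (single-cell size).
#' @return An object of class `growth_model`.
#' @export
growth_model <- function(mu_lag_min = 240, sd_lag_min = 40,
                         mu_v_um_min = 0.10, sd_v_um_min = 0.02,
                         seed_diameter_um = 1.0) {
  stopifnot(mu_v_um_min > 0, sd_lag_min >= 0, sd_v_um_min >= 0,
            seed_diameter_um > 0)
  structure(
    list(
      mu_lag_min = mu_lag_min, sd_lag_min = sd_lag_min,
      mu_v_um_min = mu_v_um_min, sd_v_um_min = sd_v_um_min,
      seed_diameter_um = seed_diameter_um
    ),
    class = "growth_model"
  )
}

#' Colony diameter at time t
#'
#' Linear radial expansion after lag: `d(t) = d0 + 2 v max(0, t - t0)`.
#' Non-decreasing in `t`, equal to the seed diameter at `t = t0`.
#'
#' @param t_min Time(s), minutes.
#' @param lag_min Per-colony lag time t0, minutes.
#' @param rate_um_min Radial growth rate v, um/min.
#' @param seed_diameter_um Seed diameter d0, um.
#' @return Diameter(s), micrometres.
#' @export
colony_diameter <- function(t_min, lag_min, rate_um_min,
                            seed_diameter_um = 1.0) {
  seed_diameter_um + 2 * rate_um_min * pmax(0, t_min - lag_min)
}

#' Synthetic plate phantom
#'
#' Seeds colony centres uniformly over the sensor field of view and draws
#' per-colony growth parameters from a [growth_model()]. Either a surface
#' density (CFU/cm^2, the primitive the assay controls; microcolony work
#' keeps it below 100 CFU/cm^2) or an explicit colony count may be given.
#' An optional hard-core minimum separation between seeds emulates a
#' well-dispersed inoculum; the default 0 allows neighbouring colonies to
#' merge as they grow.
#'
#' @param sensor A [sensor_spec()].
#' @param n_colonies Number of colonies; if `NULL`, drawn from
#'   `density_cfu_cm2` times the FOV area.
#' @param density_cfu_cm2 Surface density used when `n_colonies` is `NULL`.
#' @param growth A [growth_model()].
#' @param z_um Height of the colony plane above the pixels (default 5: cells
#'   essentially on the sensor under a thin liquid layer).
#' @param min_separation_um Hard-core minimum distance between seed centres
#'   (0 = unconstrained). Rejection-sampled; fails if infeasible.
#' @param margin_um Keep seeds at least this far from the FOV edge.
#' @param seed RNG seed; the phantom is fully determined by it.
#' @return An object of class `plate_phantom`: the sensor, `z_um`, the
#'   growth model, and a tibble `colonies` with columns `colony_id`, `x_um`,
#'   `y_um`, `lag_min`, `rate_um_min`.
#' @export
plate_phantom <- function(sensor, n_colonies = NULL, density_cfu_cm2 = 80,
                          growth = growth_model(), z_um = 5,
                          min_separation_um = 0, margin_um = 0, seed = 1L) {
  fov <- sensor_fov_um(sensor)
  if (is.null(n_colonies)) {
    area_cm2 <- prod(fov) / 1e8
    n_colonies <- max(1L, round(density_cfu_cm2 * area_cm2))
  }
  stopifnot(n_colonies >= 1, z_um >= 0, margin_um >= 0)
  rng <- local_rng(seed)
  xr <- c(margin_um, fov[1] - margin_um)
  yr <- c(margin_um, fov[2] - margin_um)
  xs <- ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n_colonies) {
    x <- stats::runif(1, xr[1], xr[2])
    y <- stats::runif(1, yr[1], yr[2])
    ok <- min_separation_um <= 0 || length(xs) == 0 ||
      min((xs - x)^2 + (ys - y)^2) >= min_separation_um^2
    if (ok) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
    tries <- tries + 1L
    if (tries > 1000L * n_colonies) {
      stop("could not place ", n_colonies, " seeds with min_separation_um = ",
           min_separation_um, " in the FOV")
    }
  }
  lag <- stats::rnorm(n_colonies, growth$mu_lag_min, growth$sd_lag_min)
  v <- truncnorm_pos(n_colonies, growth$mu_v_um_min, growth$sd_v_um_min)
  structure(
    list(
      sensor = sensor, z_um = z_um, growth = growth, seed = seed,
      colonies = tibble::tibble(
        colony_id = seq_len(n_colonies),
        x_um = xs, y_um = ys, lag_min = pmax(0, lag), rate_um_min = v
      )
    ),
    class = "plate_phantom"
  )
}

#' @export
print.plate_phantom <- function(x, ...) {
  fov <- sensor_fov_um(x$sensor)
  cat(sprintf(
    "<plate_phantom> %d colonies on %.2f x %.2f mm at z = %g um (seed %d)\n",
    nrow(x$colonies), fov[1] / 1e3, fov[2] / 1e3, x$z_um, x$seed
  ))
  invisible(x)
}

# positive-truncated normal by resampling (sd = 0 returns the mean)
truncnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= 0)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out <= 0)
  }
  out
}

# seed the global RNG for a simulation stage (documented side effect; every
# stochastic entry point takes an explicit seed so runs are reproducible)
local_rng <- function(seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  invisible(seed)
}

#' Ground-truth colony table at one or more timepoints
#'
#' True diameters from the growth law, plus the merged-component id: colonies
#' whose disks overlap (centre distance below the sum of radii) are unioned
#' into one component, mirroring the merging of neighbouring microcolonies
#' that makes a counter under-count.
#'
#' @param phantom A [plate_phantom()].
#' @param t_min Timepoint(s), minutes.
#' @return A tibble: `timepoint_min`, `colony_id`, `x_um`, `y_um`,
#'   `true_diameter_um`, `merged_component_id` (component ids are local to a
#'   timepoint, numbered by smallest member colony_id).
#' @export
phantom_ground_truth <- function(phantom, t_min) {
  g <- phantom$growth
  purrr::map_dfr(t_min, function(t) {
    co <- phantom$colonies
    d <- colony_diameter(t, co$lag_min, co$rate_um_min, g$seed_diameter_um)
    comp <- disk_components(co$x_um, co$y_um, d / 2)
    tibble::tibble(
      timepoint_min = t, colony_id = co$colony_id,
      x_um = co$x_um, y_um = co$y_um,
      true_diameter_um = d, merged_component_id = comp
    )
  })
}

# union-find over overlapping disks; component ids relabelled to
# min colony index per component
disk_components <- function(x, y, r) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if ((x[i] - x[j])^2 + (y[i] - y[j])^2 < (r[i] + r[j])^2) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, sort(unique(roots)))
}

#' Render the continuous scene at one timepoint
#'
#' Draws every colony as a radially symmetric absorbing disk with a smooth
#' sigmoidal edge on a fine transmission grid (`supersample_S` times finer
#' than the LR pixel grid). Transmission is `t_center` deep inside a colony
#' and rises to 1 across an edge of width `edge_width_um`; overlapping
#' colonies multiply their transmissions, so merged colonies form one
#' connected dark region. Background transmission is 1.
#'
#' @param phantom A [plate_phantom()].
#' @param t_min Timepoint, minutes.
#' @param supersample_S Supersampling factor relative to the LR grid; keep
#'   at least twice the reconstruction enhancement factor.
#' @param t_center Transmission at the colony centre (default 0.35).
#' @param edge_width_um Width of the sigmoidal edge (default 2).
#' @return A `scene_image`: numeric matrix (rows = y, cols = x) in [0, 1]
#'   with attributes `pitch_um` and `supersample_S`.
#' @export
render_scene <- function(phantom, t_min, supersample_S = 8,
                         t_center = 0.35, edge_width_um = 2) {
  stopifnot(t_min >= 0, supersample_S >= 1)
  sensor <- phantom$sensor
  pitch_s <- sensor$pixel_pitch_um / supersample_S
  nx <- sensor$width_px * supersample_S
  ny <- sensor$height_px * supersample_S
  scene <- matrix(1, nrow = ny, ncol = nx)
  g <- phantom$growth
  co <- phantom$colonies
  d <- colony_diameter(t_min, co$lag_min, co$rate_um_min, g$seed_diameter_um)
  # logistic edge: scale chosen so transmission traverses ~90% of its range
  # across edge_width_um
  k <- edge_width_um / (2 * log(19))
  for (i in seq_len(nrow(co))) {
    # a colony only becomes visible once its lag has elapsed
    if (d[i] <= 0 || t_min < co$lag_min[i]) next
    R <- d[i] / 2
    half <- R + 4 * edge_width_um
    cx <- co$x_um[i] / pitch_s + 0.5
    cy <- co$y_um[i] / pitch_s + 0.5
    jx <- max(1, floor(cx - half / pitch_s)):min(nx, ceiling(cx + half / pitch_s))
    jy <- max(1, floor(cy - half / pitch_s)):min(ny, ceiling(cy + half / pitch_s))
    if (length(jx) == 0 || length(jy) == 0) next
    rx <- (jx - cx) * pitch_s
    ry <- (jy - cy) * pitch_s
    r <- sqrt(outer(ry^2, rx^2, "+"))
    tt <- t_center + (1 - t_center) * stats::plogis((r - R) / k)
    scene[jy, jx] <- scene[jy, jx] * tt
  }
  structure(scene, pitch_um = pitch_s, supersample_S = supersample_S,
            class = c("scene_image", "matrix", "array"))
}

#' Noise and illumination parameters for frame capture
#'
#' @param photon_budget Expected photon count per pixel at full transmission;
#'   shot noise is Poisson at this budget. `Inf` disables shot noise.
#' @param read_noise_sd Additive Gaussian read noise, in digital numbers at
#'   the output bit depth. 0 disables it.
#' @param flat_field_amplitude Peak relative amplitude of the low-order
#'   polynomial illumination profile (default 0.05 = +/- 5%).
#' @param bit_depth Output quantization depth (default 16).
#' @return A list of class `noise_params`.
#' @export
noise_params <- function(photon_budget = 5000, read_noise_sd = 2,
                         flat_field_amplitude = 0.05, bit_depth = 16L) {
  stopifnot(photon_budget > 0, read_noise_sd >= 0,
            flat_field_amplitude >= 0, flat_field_amplitude < 1,
            bit_depth %in% c(8L, 16L))
  structure(
    list(photon_budget = photon_budget, read_noise_sd = read_noise_sd,
         flat_field_amplitude = flat_field_amplitude,
         bit_depth = as.integer(bit_depth)),
    class = "noise_params"
  )
}

#' Noise-free capture settings
#'
#' Convenience wrapper: no shot noise, no read noise, flat illumination.
#' @param bit_depth Output quantization depth.
#' @return A `noise_params` object.
#' @export
noiseless <- function(bit_depth = 16L) {
  noise_params(photon_budget = Inf, read_noise_sd = 0,
               flat_field_amplitude = 0, bit_depth = bit_depth)
}

# smooth low-order polynomial flat-field on the LR grid, fixed per phantom
flat_field_profile <- function(ny, nx, amplitude) {
  if (amplitude == 0) return(matrix(1, ny, nx))
  u <- seq(-1, 1, length.out = nx)
  v <- seq(-1, 1, length.out = ny)
  # fixed low-order shape: tilt plus curvature, normalized to peak amplitude
  f <- outer(v, u, function(y, x) 0.5 * x + 0.3 * y - 0.6 * x^2 - 0.4 * y^2 +
               0.2 * x * y)
  1 + amplitude * f / max(abs(f))
}

# bilinear sub-pixel translation of a matrix; out-of-range content clipped,
# vacated border replicated from the nearest valid sample
shift_bilinear <- function(m, dy, dx) {
  if (dy == 0 && dx == 0) return(m)
  ny <- nrow(m); nx <- ncol(m)
  ys <- pmin(pmax(seq_len(ny) - dy, 1), ny)
  xs <- pmin(pmax(seq_len(nx) - dx, 1), nx)
  y0 <- floor(ys); y1 <- pmin(y0 + 1, ny); wy <- ys - y0
  x0 <- floor(xs); x1 <- pmin(x0 + 1, nx); wx <- xs - x0
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  c_ <- m[y1, x0, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
  top <- a * (1 - wx)[col(a)] + b * wx[col(b)]
  bot <- c_ * (1 - wx)[col(c_)] + d * wx[col(d)]
  top * (1 - wy)[row(top)] + bot * wy[row(bot)]
}

# box-average an S-times supersampled matrix down to the LR grid
downsample_box <- function(m, S) {
  if (S == 1) return(m)
  ny <- nrow(m) / S; nx <- ncol(m) / S
  stopifnot(ny == round(ny), nx == round(nx))
  # average over S rows then S cols via dimension folding
  dim(m) <- c(S, ny, ncol(m))
  m <- colMeans(m)                       # ny x (nx*S)
  m <- t(m)
  dim(m) <- c(S, nx, ny)
  t(colMeans(m))                         # ny x nx
}

#' Capture one low-resolution frame
#'
#' Simulates what the pixel array records under one illumination position:
#' the scene is translated by the physical shadow shift for the source and
#' sample height, blurred slightly to emulate diffraction of the shadow over
#' the sample-to-sensor gap (Gaussian, sigma = 0.03 um per um of height),
#' integrated over each LR pixel footprint (box average of the supersampled
#' grid), multiplied by the flat-field illumination profile, and corrupted
#' by Poisson shot noise and Gaussian read noise before quantization.
#'
#' @param scene A `scene_image` from [render_scene()].
#' @param source_xy_mm Source lateral offset (Lx, Ly), mm.
#' @param source_height_mm Source height, mm.
#' @param z_um Sample height, micrometres.
#' @param sensor A [sensor_spec()].
#' @param noise A [noise_params()] (use [noiseless()] for clean frames).
#' @param blur_sigma_um_per_um Diffraction-proxy blur growth rate with
#'   height (default 0.03, i.e. 0.3 um of sigma per 10 um of gap).
#' @return Integer matrix (`height_px` x `width_px`) of quantized pixel
#'   values in `[0, 2^bit_depth - 1]`.
#' @export
capture_frame <- function(scene, source_xy_mm, source_height_mm, z_um, sensor,
                          noise = noise_params(),
                          blur_sigma_um_per_um = 0.03) {
  S <- attr(scene, "supersample_S")
  pitch_s <- attr(scene, "pitch_um")
  if (nrow(scene) != sensor$height_px * S ||
      ncol(scene) != sensor$width_px * S) {
    stop("scene grid does not match the sensor dimensions")
  }
  shift_px <- compute_shadow_shift(source_xy_mm, source_height_mm, z_um, sensor)
  shifted <- shift_bilinear(scene, shift_px["dy"] * S, shift_px["dx"] * S)
  sigma_um <- blur_sigma_um_per_um * z_um
  sigma_px <- sigma_um / pitch_s
  if (sigma_px > 0.3) {
    shifted <- eb_gblur(shifted, sigma_px)
  }
  lr <- downsample_box(shifted, S)
  lr <- lr * flat_field_profile(nrow(lr), ncol(lr), noise$flat_field_amplitude)
  full_scale <- 2^noise$bit_depth - 1
  if (is.finite(noise$photon_budget)) {
    lam <- pmax(lr, 0) * noise$photon_budget
    lr <- matrix(stats::rpois(length(lam), lam), nrow(lr)) / noise$photon_budget
  }
  dn <- lr * full_scale
  if (noise$read_noise_sd > 0) {
    dn <- dn + stats::rnorm(length(dn), 0, noise$read_noise_sd)
  }
  out <- matrix(as.integer(pmin(pmax(round(dn), 0), full_scale)), nrow(dn))
  out
}

#' Simulate a full time-lapse acquisition
#'
#' For each timepoint, renders the scene and captures one LR frame per
#' schedule entry (a `frame_stack`), alongside the ground-truth colony
#' table. Images are taken at fixed intervals, mirroring incubator
#' acquisition every 20 minutes. Deterministic given the phantom seed.
#'
#' @param phantom A [plate_phantom()].
#' @param schedule A [scan_schedule()].
#' @param t_start_min,t_end_min Acquisition window, minutes.
#' @param interval_min Spacing between timepoints (default 20, > 0).
#' @param noise A [noise_params()].
#' @param supersample_S Scene supersampling factor.
#' @param ... Passed to [render_scene()] (edge profile) and
#'   [capture_frame()] (blur rate).
#' @return A list of class `timelapse`: `stacks` (list of `frame_stack`
#'   objects, one per timepoint), `ground_truth` (tibble), `schedule`,
#'   `sensor`, `z_um`.
#' @export
simulate_timelapse <- function(phantom, schedule, t_start_min, t_end_min,
                               interval_min = 20, noise = noise_params(),
                               supersample_S = 8, ...) {
  if (interval_min <= 0) stop("interval_min must be positive")
  stopifnot(t_end_min >= t_start_min)
  times <- seq(t_start_min, t_end_min, by = interval_min)
  local_rng(phantom$seed + 1L)
  dots <- list(...)
  render_args <- dots[intersect(names(dots), c("t_center", "edge_width_um"))]
  capture_args <- dots[intersect(names(dots), "blur_sigma_um_per_um")]
  stacks <- purrr::map(times, function(t) {
    scene <- do.call(render_scene,
                     c(list(phantom, t, supersample_S), render_args))
    frames <- purrr::map2(
      schedule$source_x_mm, schedule$source_y_mm,
      function(lx, ly) {
        do.call(capture_frame,
                c(list(scene, c(lx, ly), attr(schedule, "source_height_mm"),
                       phantom$z_um, phantom$sensor, noise), capture_args))
      }
    )
    frame_stack(frames, schedule, t, noise$bit_depth)
  })
  structure(
    list(
      stacks = stacks,
      ground_truth = phantom_ground_truth(phantom, times),
      schedule = schedule, sensor = phantom$sensor, z_um = phantom$z_um
    ),
    class = "timelapse"
  )
}

#' Frame stack: the LR observations at one timepoint
#'
#' @param frames List of integer LR matrices, one per schedule entry.
#' @param schedule The [scan_schedule()] the frames were captured under.
#' @param timestamp_min Acquisition time, minutes.
#' @param bit_depth Pixel bit depth.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, schedule, timestamp_min, bit_depth = 16L) {
  stopifnot(length(frames) == nrow(schedule))
  structure(
    list(frames = frames, schedule = schedule,
         timestamp_min = timestamp_min, bit_depth = as.integer(bit_depth)),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d frame(s) of %d x %d px, t = %g min\n",
              length(x$frames), d[2], d[1], x$timestamp_min))
  invisible(x)
}
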