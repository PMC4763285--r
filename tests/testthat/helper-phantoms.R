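# fixtures built in code: small sensors, degenerate growth models, and a
# capture helper shared across test files

tiny_sensor <- function(n = 100) sensor_spec(n, n)

# growth model that renders fixed-diameter disks at t = 0 (no lag, no growth)
static_disks <- function(diameter_um) {
  growth_model(mu_lag_min = 0, sd_lag_min = 0, mu_v_um_min = 1e-9,
               sd_v_um_min = 0, seed_diameter_um = diameter_um)
}

# place explicit colony centres with a fixed-diameter model
disk_phantom <- function(sensor, x_um, y_um, diameter_um, z_um = 5, seed = 1) {
  ph <- plate_phantom(sensor, n_colonies = length(x_um), z_um = z_um,
                      seed = seed, growth = static_disks(diameter_um))
  ph$colonies$x_um <- x_um
  ph$colonies$y_um <- y_um
  ph
}

# capture every frame of a schedule from one scene
capture_stack <- function(scene, schedule, z_um, sensor,
                          noise = noiseless(), t_min = 0) {
  frames <- lapply(seq_len(nrow(schedule)), function(i) {
    capture_frame(scene, c(schedule$source_x_mm[i], schedule$source_y_mm[i]),
                  attr(schedule, "source_height_mm"), z_um, sensor, noise)
  })
  frame_stack(frames, schedule, t_min, noise$bit_depth)
}

# brute-force ray-trace of the shadow position: parametric line from the
# source through an object point at height z, intersected with z = 0
raytrace_shift_px <- function(lx_mm, ly_mm, h_mm, z_um, pitch_um,
                              x0_um = 0, y0_um = 0) {
  src <- c(lx_mm * 1e3, ly_mm * 1e3, h_mm * 1e3)
  obj <- c(x0_um, y0_um, z_um)
  t_hit <- src[3] / (src[3] - obj[3])
  hit <- src + t_hit * (obj - src)
  (hit[1:2] - obj[1:2]) / pitch_um
}
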