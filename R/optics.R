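#' Sensor specification
#'
#' Describes the pixel array of a lensless shadow-imaging sensor: the sample
#' sits directly on the pixels and its transmission shadow is sampled at the
#' pixel pitch. The default pitch of 2.2 um matches a typical 5-megapixel
#' CMOS sensor used for on-chip microscopy; raw resolution is Nyquist-limited
#' to about twice the pitch.
#'
#' Coordinates are right-handed with the origin at the top-left pixel corner:
#' x rightward along the width, y downward along the height, z upward from
#' the sensor plane. All lengths are micrometres internally; interfaces that
#' take millimetres say so in the argument name.
#'
#' @param width_px,height_px Sensor dimensions in pixels.
#' @param pixel_pitch_um Pixel pitch in micrometres (default 2.2).
#' @return An object of class `sensor_spec`.
#' @examples
#' sensor_spec(2591, 1954)  # 5.7 mm x 4.3 mm imaging area
#' @export
sensor_spec <- function(width_px, height_px, pixel_pitch_um = 2.2) {
  stopifnot(pixel_pitch_um > 0, width_px >= 1, height_px >= 1)
  structure(
    list(
      width_px = as.integer(width_px),
      height_px = as.integer(height_px),
      pixel_pitch_um = pixel_pitch_um
    ),
    class = "sensor_spec"
  )
}

#' @export
print.sensor_spec <- function(x, ...) {
  fov <- sensor_fov_um(x)
  cat(sprintf(
    "<sensor_spec> %d x %d px @ %.3g um pitch (FOV %.3g x %.3g mm, %.3g mm^2)\n",
    x$width_px, x$height_px, x$pixel_pitch_um,
    fov[1] / 1e3, fov[2] / 1e3, prod(fov) / 1e6
  ))
  invisible(x)
}

#' Physical field of view of a sensor
#'
#' @param sensor A [sensor_spec()].
#' @return Named numeric `c(x_um, y_um)`: the physical extent of the pixel
#'   array (pitch times pixel count per axis).
#' @export
sensor_fov_um <- function(sensor) {
  c(
    x_um = sensor$pixel_pitch_um * sensor$width_px,
    y_um = sensor$pixel_pitch_um * sensor$height_px
  )
}

#' Field-of-view area in mm^2
#'
#' @param sensor A [sensor_spec()].
#' @return Area of the imaging region in square millimetres.
#' @export
sensor_fov_area_mm2 <- function(sensor) {
  fov <- sensor_fov_um(sensor)
  unname(prod(fov)) / 1e6
}

#' Shadow displacement of a plane at height z
#'
#' The quantity sub-pixel sweeping exploits: a point source at lateral offset
#' (Lx, Ly) and height H above the sensor casts the shadow of an object at
#' height z displaced, by similar triangles, by `-(z / (H - z)) * (Lx, Ly)`
#' physically; dividing by the pixel pitch gives the displacement in
#' low-resolution pixel units. A positive lateral source offset moves the
#' shadow in the negative direction. The exact `z / (H - z)` form is used
#' rather than the small-z approximation `z / H`.
#'
#' The shift is treated as global across the field of view (the slight
#' field-position dependence is neglected, as shift-and-add assumes one
#' shift per frame).
#'
#' @param source_xy_mm Numeric length-2: lateral source offset (Lx, Ly) in mm
#'   relative to the sensor centre.
#' @param source_height_mm Source height H above the sensor plane, mm.
#' @param z_um Sample height above the pixels, micrometres. Must satisfy
#'   `0 <= z_um < 1000 * source_height_mm`.
#' @param sensor A [sensor_spec()] (supplies the pixel pitch).
#' @return Named numeric `c(dx, dy)`: the shadow shift in LR pixel units.
#' @examples
#' s <- sensor_spec(100, 100)
#' compute_shadow_shift(c(20, 0), 100, 100, s)  # ~ -9.10 px in x
#' @export
compute_shadow_shift <- function(source_xy_mm, source_height_mm, z_um, sensor) {
  stopifnot(length(source_xy_mm) == 2, is.finite(source_xy_mm),
            source_height_mm > 0)
  if (z_um < 0) stop("sample height z_um must be non-negative")
  H_um <- source_height_mm * 1e3
  if (z_um >= H_um) {
    stop("sample height z_um must be below the source height")
  }
  shift_um <- -(z_um / (H_um - z_um)) * source_xy_mm * 1e3
  c(dx = shift_um[1], dy = shift_um[2]) / sensor$pixel_pitch_um
}

#' Scan schedule of illumination source positions
#'
#' One source position per low-resolution frame within an acquisition. All
#' positions within a schedule share the source height.
#'
#' @param source_x_mm,source_y_mm Lateral offsets of each source position,
#'   mm relative to the sensor centre.
#' @param source_height_mm Common source height, mm.
#' @return A tibble of class `scan_schedule` with columns `frame`,
#'   `source_x_mm`, `source_y_mm` and attribute `source_height_mm`.
#' @export
scan_schedule <- function(source_x_mm, source_y_mm, source_height_mm) {
  stopifnot(length(source_x_mm) == length(source_y_mm),
            length(source_x_mm) >= 1, source_height_mm > 0)
  out <- tibble::tibble(
    frame = seq_along(source_x_mm),
    source_x_mm = as.numeric(source_x_mm),
    source_y_mm = as.numeric(source_y_mm)
  )
  attr(out, "source_height_mm") <- source_height_mm
  class(out) <- c("scan_schedule", class(out))
  out
}

#' Shadow shifts for every frame of a schedule
#'
#' Applies [compute_shadow_shift()] to each source position and reports the
#' maximum shift increment between consecutive frames (used to validate that
#' a sweep is genuinely sub-pixel).
#'
#' @param schedule A [scan_schedule()].
#' @param z_um Sample height, micrometres.
#' @param sensor A [sensor_spec()].
#' @return A tibble with columns `frame`, `dx`, `dy` (LR pixel units) and
#'   attribute `max_increment_px`, the largest Chebyshev step between
#'   consecutive shifts.
#' @export
schedule_shifts <- function(schedule, z_um, sensor) {
  H <- attr(schedule, "source_height_mm")
  shifts <- purrr::map2(
    schedule$source_x_mm, schedule$source_y_mm,
    function(lx, ly) compute_shadow_shift(c(lx, ly), H, z_um, sensor)
  )
  out <- tibble::tibble(
    frame = schedule$frame,
    dx = purrr::map_dbl(shifts, 1),
    dy = purrr::map_dbl(shifts, 2)
  )
  inc <- if (nrow(out) > 1) {
    max(pmax(abs(diff(out$dx)), abs(diff(out$dy))))
  } else 0
  attr(out, "max_increment_px") <- inc
  out
}

#' Design a source grid for a target enhancement factor
#'
#' Inverts the similar-triangles shift relation to find the lateral source
#' spacing at which consecutive shadow shifts step by exactly `1/E` LR
#' pixels at sample height `z_um`:
#' `spacing = pitch * (H - z) / (z * E)`.
#' Returns a `grid_n` x `grid_n` grid of source positions centred on the
#' optical axis, serpentine-ordered row by row so consecutive frames always
#' differ by one grid step.
#'
#' @param sensor A [sensor_spec()].
#' @param z_um Sample height the sweep is designed for, micrometres (> 0).
#' @param enhancement_E Integer enhancement factor E (>= 1).
#' @param grid_n Sources per side (>= 1).
#' @param source_height_mm Source height H, mm (default 80).
#' @return A [scan_schedule()].
#' @examples
#' s <- sensor_spec(100, 100)
#' sched <- design_scan(s, z_um = 100, enhancement_E = 4, grid_n = 8)
#' attr(schedule_shifts(sched, 100, s), "max_increment_px")  # 0.25
#' @export
design_scan <- function(sensor, z_um, enhancement_E, grid_n,
                        source_height_mm = 80) {
  stopifnot(enhancement_E >= 1, grid_n >= 1, source_height_mm > 0)
  if (grid_n == 1) {
    return(scan_schedule(0, 0, source_height_mm))
  }
  if (z_um <= 0) {
    stop("cannot design a sweep for z_um = 0: any spacing gives zero shift")
  }
  H_um <- source_height_mm * 1e3
  spacing_um <- sensor$pixel_pitch_um * (H_um - z_um) / (z_um * enhancement_E)
  offsets_mm <- (seq_len(grid_n) - (grid_n + 1) / 2) * spacing_um / 1e3
  grid <- tidyr::crossing(iy = seq_len(grid_n), ix = seq_len(grid_n))
  # serpentine order: reverse x on even rows so consecutive steps are 1 apart
  grid <- dplyr::mutate(
    grid,
    ix = ifelse(.data$iy %% 2 == 0, grid_n + 1 - .data$ix, .data$ix)
  )
  scan_schedule(offsets_mm[grid$ix], offsets_mm[grid$iy], source_height_mm)
}

#' Serialize a scan schedule and sensor to a JSON sidecar
#'
#' @param schedule A [scan_schedule()].
#' @param sensor A [sensor_spec()].
#' @param path File to write.
#' @param extra Named list of extra fields to merge into the sidecar
#'   (unknown fields are preserved on round-trip).
#' @return `path`, invisibly.
#' @export
write_scan_sidecar <- function(schedule, sensor, path, extra = list()) {
  meta <- c(
    list(
      pixel_pitch_um = sensor$pixel_pitch_um,
      width_px = sensor$width_px,
      height_px = sensor$height_px,
      source_height_mm = attr(schedule, "source_height_mm"),
      sources = unname(purrr::map2(
        schedule$source_x_mm, schedule$source_y_mm, c
      ))
    ),
    extra
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scan schedule and sensor from a JSON sidecar
#'
#' @param path Sidecar file written by [write_scan_sidecar()].
#' @return A list with elements `sensor`, `schedule`, and `extra` (any
#'   fields beyond the schema, preserved verbatim).
#' @export
read_scan_sidecar <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("pixel_pitch_um", "width_px", "height_px",
                "source_height_mm", "sources")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    stop("sidecar ", path, " is missing required field(s): ",
         paste(missing, collapse = ", "))
  }
  src <- meta$sources
  if (is.null(dim(src))) src <- matrix(unlist(src), ncol = 2, byrow = TRUE)
  list(
    sensor = sensor_spec(meta$width_px, meta$height_px, meta$pixel_pitch_um),
    schedule = scan_schedule(src[, 1], src[, 2], meta$source_height_mm),
    extra = meta[setdiff(names(meta), required)]
  )
}
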