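#' Write a frame stack as multi-page TIFF with a JSON sidecar
#'
#' One TIFF page per illumination position, at the stack's bit depth; the
#' sidecar carries the sensor geometry, the source schedule, the timestamp
#' and any extra fields (noise settings, seeds) verbatim.
#'
#' @param stack A [frame_stack()].
#' @param sensor A [sensor_spec()].
#' @param path TIFF path (conventionally `t####min.tif`).
#' @param sidecar_path JSON path; default `path` with `.json` extension.
#' @param extra Named list merged into the sidecar (preserved on read).
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, sensor, path,
                              sidecar_path = sub("\\.tiff?$", ".json", path),
                              extra = list()) {
  full_scale <- 2^stack$bit_depth - 1
  pages <- purrr::map(stack$frames, function(f) f / full_scale)
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth)
  write_scan_sidecar(
    stack$schedule, sensor, sidecar_path,
    extra = c(list(timestamp_min = stack$timestamp_min,
                   bit_depth = stack$bit_depth), extra)
  )
  invisible(path)
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param path Multi-page TIFF path.
#' @param sidecar_path JSON sidecar path; default derived from `path`.
#' @return A list: `stack` (a [frame_stack()]), `sensor`, `extra` (sidecar
#'   fields beyond the schema).
#' @export
read_frame_stack <- function(path,
                             sidecar_path = sub("\\.tiff?$", ".json", path)) {
  if (!file.exists(sidecar_path)) {
    stop("missing sidecar: ", sidecar_path)
  }
  meta <- read_scan_sidecar(sidecar_path)
  bit_depth <- meta$extra$bit_depth %||% 16L
  timestamp <- meta$extra$timestamp_min %||% NA_real_
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  full_scale <- 2^bit_depth - 1
  frames <- purrr::map(pages, function(p) {
    matrix(as.integer(round(p * full_scale)), nrow(p))
  })
  if (length(frames) != nrow(meta$schedule)) {
    stop("sidecar schedule (", nrow(meta$schedule),
         " sources) does not match TIFF page count (", length(frames), ")")
  }
  list(
    stack = frame_stack(frames, meta$schedule, timestamp, bit_depth),
    sensor = meta$sensor,
    extra = meta$extra[setdiff(names(meta$extra),
                               c("bit_depth", "timestamp_min"))]
  )
}

#' Write an HR image as 32-bit float TIFF with a sidecar
#'
#' @param image An [hr_image()].
#' @param path TIFF path.
#' @param sidecar_path JSON path; default derived from `path`.
#' @return `path`, invisibly.
#' @export
write_hr <- function(image, path,
                     sidecar_path = sub("\\.tiff?$", ".json", path)) {
  m <- strip_image(image)
  # float TIFF expects [0,1]-ish but stores any float; normalize scale is
  # preserved in the sidecar
  tiff::writeTIFF(m / max(m, 1), path, bits.per.sample = 32L,
                  reduce = FALSE)
  jsonlite::write_json(
    list(enhancement_E = attr(image, "enhancement_E"),
         hr_pitch_um = attr(image, "hr_pitch_um"),
         focal_z_um = attr(image, "focal_z_um"),
         timestamp_min = attr(image, "timestamp_min"),
         scale = max(m, 1)),
    sidecar_path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read an HR image written by [write_hr()]
#'
#' @param path TIFF path.
#' @param sidecar_path JSON sidecar path.
#' @return An [hr_image()].
#' @export
read_hr <- function(path, sidecar_path = sub("\\.tiff?$", ".json", path)) {
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  m <- tiff::readTIFF(path) * (meta$scale %||% 1)
  hr_image(m, meta$enhancement_E, meta$hr_pitch_um,
           meta$focal_z_um %||% NA_real_, meta$timestamp_min %||% NA_real_)
}

#' Write / read colony region tables as CSV
#'
#' Plain CSV round-trip of [segment_colonies()] output; columns beyond the
#' documented schema are preserved.
#'
#' @param regions A `colony_regions` tibble (possibly several timepoints).
#' @param path CSV path.
#' @return `path` invisibly (write); a `colony_regions` tibble (read).
#' @export
write_regions_csv <- function(regions, path) {
  utils::write.csv(as.data.frame(regions), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_regions_csv
#' @export
read_regions_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "area_um2", "equivalent_diameter_um", "x_um", "y_um")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("regions CSV ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  out <- tibble::as_tibble(df)
  class(out) <- c("colony_regions", class(out))
  out
}

#' Write the phantom ground-truth table as CSV
#'
#' @param ground_truth Tibble from [phantom_ground_truth()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_csv <- function(ground_truth, path) {
  utils::write.csv(as.data.frame(ground_truth), path, row.names = FALSE)
  invisible(path)
}
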