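#' Pipeline configuration
#'
#' Builds the full configuration for an end-to-end run (simulate ->
#' reconstruct -> segment -> track -> report) with every default recorded.
#' Keys carry explicit unit suffixes (`_um`, `_mm`, `_min`) to keep units
#' honest. Any subset of settings can be overridden via `...` using the
#' same nested names; [read_pipeline_config()] does the same from YAML.
#'
#' @param ... Named overrides, e.g. `sensor = list(width_px = 300)`,
#'   `phantom = list(n_colonies = 10, seed = 7)`.
#' @return A nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    version = 1L,
    sensor = list(width_px = 2591L, height_px = 1954L, pixel_pitch_um = 2.2),
    scan = list(source_height_mm = 80, grid_n = 8L, enhancement_E = 4L),
    phantom = list(
      n_colonies = NULL, density_cfu_cm2 = 80, z_um = 5,
      min_separation_um = 0, margin_um = 50, seed = 1L,
      growth = list(mu_lag_min = 240, sd_lag_min = 40,
                    mu_v_um_min = 0.10, sd_v_um_min = 0.02,
                    seed_diameter_um = 1.0),
      noise = list(photon_budget = 5000, read_noise_sd = 2,
                   flat_field_amplitude = 0.05, bit_depth = 16L),
      supersample_S = 8L
    ),
    acquisition = list(t_start_min = 0, t_end_min = 720, interval_min = 20),
    reconstruction = list(z_um = 5, autofocus = NULL),
    segmentation = list(min_diameter_um = 20, closing_radius_um = 2,
                        min_region_area_um2 = 20,
                        background_scale_um = 200, border_policy = "flag"),
    tracking = list(max_link_distance_um = 15),
    titer = list(sample_volume_ul = NULL, dilution_factor = 1),
    output_dir = "microcolony_run"
  )
  structure(modify_nested(defaults, list(...)), class = "pipeline_config")
}

# recursive merge of named lists (overrides win; unknown keys rejected)
modify_nested <- function(base, overrides) {
  for (nm in names(overrides)) {
    if (!nm %in% names(base)) {
      stop("unknown configuration key: ", nm)
    }
    if (is.list(base[[nm]]) && is.list(overrides[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- modify_nested(base[[nm]], overrides[[nm]])
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  overrides <- yaml::read_yaml(path)
  if (is.null(overrides)) overrides <- list()
  do.call(pipeline_config, overrides)
}

#' Write a pipeline configuration to YAML
#'
#' @param config A `pipeline_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full microcolony-counting pipeline
#'
#' Executes simulate -> reconstruct -> segment -> track -> report according
#' to a [pipeline_config()], writing every artifact (LR stacks + sidecars,
#' HR TIFFs, region CSVs, ground truth, report JSON) under
#' `config$output_dir`, and returns a run manifest with the config
#' snapshot, per-file MD5 hashes and timings. Deterministic for a fixed
#' `config$phantom$seed`.
#'
#' Stages may be skipped: with `stages` not containing `"simulate"`,
#' `hr_dir` must point at existing HR TIFF/sidecar pairs to segment.
#'
#' @param config A `pipeline_config`.
#' @param stages Character subset of
#'   `c("simulate", "reconstruct", "segment", "track", "report")`.
#' @param hr_dir Directory of pre-computed HR images (segmentation-only
#'   runs).
#' @param quiet Suppress progress messages.
#' @return A list of class `run_manifest`: `config`, `version`, `stages`,
#'   `artifacts` (tibble: `stage`, `file`, `md5`), `timings_s`, `report`
#'   (the `timeseries_report`, when produced), `tracks`, `regions`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "reconstruct", "segment",
                                    "track", "report"),
                         hr_dir = NULL, quiet = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  artifacts <- list()
  timings <- c()
  note <- function(stage, files) {
    artifacts[[length(artifacts) + 1]] <<- tibble::tibble(
      stage = stage, file = files, md5 = unname(tools::md5sum(files))
    )
  }
  sensor <- sensor_spec(config$sensor$width_px, config$sensor$height_px,
                        config$sensor$pixel_pitch_um)
  schedule <- design_scan(
    sensor, config$phantom$z_um, config$scan$enhancement_E,
    config$scan$grid_n, config$scan$source_height_mm
  )
  hr_images <- NULL

  if ("simulate" %in% stages) {
    t0 <- proc.time()[3]
    if (is.null(config$phantom$seed)) stop("simulate requires a seed")
    growth <- do.call(growth_model, config$phantom$growth)
    noise <- do.call(noise_params, config$phantom$noise)
    phantom <- plate_phantom(
      sensor, n_colonies = config$phantom$n_colonies,
      density_cfu_cm2 = config$phantom$density_cfu_cm2,
      growth = growth, z_um = config$phantom$z_um,
      min_separation_um = config$phantom$min_separation_um,
      margin_um = config$phantom$margin_um, seed = config$phantom$seed
    )
    tl <- simulate_timelapse(
      phantom, schedule, config$acquisition$t_start_min,
      config$acquisition$t_end_min, config$acquisition$interval_min,
      noise = noise, supersample_S = config$phantom$supersample_S
    )
    files <- character()
    for (st in tl$stacks) {
      f <- file.path(config$output_dir,
                     sprintf("t%04dmin.tif", as.integer(round(st$timestamp_min))))
      write_frame_stack(st, sensor, f,
                        extra = list(rng_seed = config$phantom$seed,
                                     noise_params = config$phantom$noise))
      files <- c(files, f, sub("\\.tif$", ".json", f))
    }
    gt_path <- file.path(config$output_dir, "ground_truth.csv")
    write_ground_truth_csv(tl$ground_truth, gt_path)
    note("simulate", c(files, gt_path))
    timings["simulate"] <- proc.time()[3] - t0
    say("simulate: %d timepoints, %d colonies", length(tl$stacks),
        nrow(phantom$colonies))
    stacks <- tl$stacks
  } else {
    stacks <- NULL
  }

  if ("reconstruct" %in% stages) {
    t0 <- proc.time()[3]
    if (is.null(stacks)) {
      stack_files <- sort(list.files(config$output_dir, "^t[0-9]+min\\.tif$",
                                     full.names = TRUE))
      stacks <- purrr::map(stack_files, function(f) read_frame_stack(f)$stack)
    }
    E <- config$scan$enhancement_E
    hr_images <- purrr::map(stacks, function(st) {
      if (!is.null(config$reconstruction$autofocus)) {
        af <- config$reconstruction$autofocus
        res <- autofocus(st, sensor,
                         seq(af$z_min_um, af$z_max_um, af$z_step_um), E)
        res$image
      } else {
        reconstruct_at(st, sensor, config$reconstruction$z_um, E)
      }
    })
    files <- character()
    for (im in hr_images) {
      f <- file.path(config$output_dir,
                     sprintf("hr_t%04dmin.tif", as.integer(round(attr(im, "timestamp_min")))))
      write_hr(im, f)
      files <- c(files, f, sub("\\.tif$", ".json", f))
    }
    note("reconstruct", files)
    timings["reconstruct"] <- proc.time()[3] - t0
    say("reconstruct: %d HR images (E = %d)", length(hr_images), E)
  }

  regions <- NULL
  if ("segment" %in% stages) {
    t0 <- proc.time()[3]
    if (is.null(hr_images)) {
      src <- hr_dir %||% config$output_dir
      hr_files <- sort(list.files(src, "^hr_.*\\.tif$", full.names = TRUE))
      if (length(hr_files) == 0) stop("no HR images found in ", src)
      hr_images <- purrr::map(hr_files, read_hr)
    }
    sp <- segmentation_params(
      background_scale_um = config$segmentation$background_scale_um,
      closing_radius_um = config$segmentation$closing_radius_um,
      min_region_area_um2 = config$segmentation$min_region_area_um2,
      min_diameter_um = config$segmentation$min_diameter_um,
      border_policy = config$segmentation$border_policy
    )
    regions <- dplyr::bind_rows(purrr::map(hr_images, segment_colonies,
                                           params = sp))
    class(regions) <- c("colony_regions", class(regions))
    f <- file.path(config$output_dir, "regions.csv")
    write_regions_csv(regions, f)
    note("segment", f)
    timings["segment"] <- proc.time()[3] - t0
    say("segment: %d regions over %d timepoints", nrow(regions),
        length(unique(regions$timepoint_min)))
  }

  tracks <- NULL
  if ("track" %in% stages) {
    t0 <- proc.time()[3]
    if (is.null(regions)) {
      regions <- read_regions_csv(file.path(config$output_dir, "regions.csv"))
    }
    tracks <- link_tracks(regions, config$tracking$max_link_distance_um)
    f <- file.path(config$output_dir, "tracks.csv")
    utils::write.csv(as.data.frame(tracks), f, row.names = FALSE)
    note("track", f)
    timings["track"] <- proc.time()[3] - t0
    say("track: %d tracks, %d merges", length(unique(tracks$track_id)),
        nrow(attr(tracks, "merges")))
  }

  report <- NULL
  if ("report" %in% stages) {
    t0 <- proc.time()[3]
    src <- tracks %||% regions
    if (is.null(src)) stop("report stage needs tracked or segmented regions")
    report <- timeseries_report(
      src, sensor,
      sample_volume_ul = config$titer$sample_volume_ul,
      dilution_factor = config$titer$dilution_factor
    )
    f <- file.path(config$output_dir, "report.json")
    jsonlite::write_json(
      list(per_timepoint = report$per_timepoint,
           saturation_time_min = report$saturation_time_min,
           final_count = report$final_count,
           density_cfu_cm2 = report$density_cfu_cm2,
           titer_cfu_ml = report$titer_cfu_ml),
      f, auto_unbox = TRUE, digits = NA, na = "null"
    )
    fc <- file.path(config$output_dir, "per_timepoint.csv")
    utils::write.csv(as.data.frame(report$per_timepoint), fc,
                     row.names = FALSE)
    note("report", c(f, fc))
    timings["report"] <- proc.time()[3] - t0
    say("report: final count %d, saturation %g min", report$final_count,
        report$saturation_time_min)
  }

  manifest <- structure(
    list(config = config, version = as.character(utils::packageVersion("microcolony")),
         stages = stages,
         artifacts = dplyr::bind_rows(artifacts),
         timings_s = timings, report = report, tracks = tracks,
         regions = regions, created = format(Sys.time(), tz = "UTC")),
    class = "run_manifest"
  )
  jsonlite::write_json(
    list(version = manifest$version, stages = stages,
         created = manifest$created,
         config = unclass(config),
         artifacts = manifest$artifacts,
         timings_s = as.list(timings)),
    file.path(config$output_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> stages: %s\n", paste(x$stages, collapse = " -> ")))
  cat(sprintf("  %d artifact(s) under %s\n", nrow(x$artifacts),
              x$config$output_dir))
  invisible(x)
}
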