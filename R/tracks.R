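#' Link colony regions across timepoints into tracks
#'
#' Greedy nearest-centroid linking between consecutive timepoints: candidate
#' (track, region) pairs are considered closest-first, each track and each
#' region is matched at most once, and candidates beyond `max_link_distance_um`
#' are rejected. Unmatched regions start new tracks. When two or more live
#' tracks contend for the same region (their nearest admissible region is
#' one that another track claimed), the contenders have merged: the
#' largest-area track survives and carries the region onward, the others
#' record `merged_into` at that timepoint. Colony centroids barely move
#' between 20-min frames, so this simple rule is sufficient at microcolony
#' densities.
#'
#' @param regions_by_time A `colony_regions` tibble covering several
#'   timepoints (or list of per-timepoint tibbles, which will be bound).
#'   `timepoint_min` must be populated; labels must be unique within a
#'   timepoint.
#' @param max_link_distance_um Gate distance for linking (default 15).
#' @return A tibble of class `colony_tracks`: one row per (track, timepoint)
#'   observation with columns `track_id`, `timepoint_min`, `label`, `x_um`,
#'   `y_um`, `area_um2`, `equivalent_diameter_um`, `counted`. Attributes:
#'   `merges` (tibble `track_id`, `merged_into`, `merge_time_min`) and
#'   `births` (tibble `track_id`, `birth_time_min`).
#' @export
link_tracks <- function(regions_by_time, max_link_distance_um = 15) {
  if (is.list(regions_by_time) && !is.data.frame(regions_by_time)) {
    regions_by_time <- dplyr::bind_rows(regions_by_time)
  }
  need <- c("timepoint_min", "label", "x_um", "y_um", "area_um2",
            "equivalent_diameter_um", "counted")
  stopifnot(all(need %in% names(regions_by_time)))
  dup <- dplyr::count(regions_by_time, .data$timepoint_min, .data$label)
  if (any(dup$n > 1)) stop("duplicate labels within a timepoint")
  times <- sort(unique(regions_by_time$timepoint_min))
  obs <- list()
  merges <- tibble::tibble(track_id = integer(), merged_into = integer(),
                           merge_time_min = numeric())
  births <- tibble::tibble(track_id = integer(), birth_time_min = numeric())
  next_id <- 1L
  # live state: track_id, x, y, area of the latest observation
  live <- tibble::tibble(track_id = integer(), x_um = numeric(),
                         y_um = numeric(), area_um2 = numeric())
  for (t in times) {
    cur <- dplyr::filter(regions_by_time, .data$timepoint_min == t)
    assigned_track <- rep(NA_integer_, nrow(cur))
    if (nrow(live) > 0 && nrow(cur) > 0) {
      pairs <- tidyr::crossing(ti = seq_len(nrow(live)),
                               ri = seq_len(nrow(cur)))
      pairs$dist <- sqrt(
        (live$x_um[pairs$ti] - cur$x_um[pairs$ri])^2 +
          (live$y_um[pairs$ti] - cur$y_um[pairs$ri])^2
      )
      pairs <- dplyr::arrange(
        dplyr::filter(pairs, .data$dist <= max_link_distance_um),
        .data$dist
      )
      track_used <- rep(FALSE, nrow(live))
      region_used <- rep(FALSE, nrow(cur))
      region_of_track <- rep(NA_integer_, nrow(live))
      for (k in seq_len(nrow(pairs))) {
        ti <- pairs$ti[k]; ri <- pairs$ri[k]
        if (!track_used[ti] && !region_used[ri]) {
          track_used[ti] <- TRUE
          region_used[ri] <- TRUE
          region_of_track[ti] <- ri
        }
      }
      # Merge resolution: a live track left unmatched may have been
      # absorbed by a neighbour. Overlap gate: the merged region's centroid
      # can jump by up to the colony separation, so candidates are regions
      # within the sum of equivalent radii (or the link gate if larger).
      # The largest-area contender survives; displaced tracks re-enter the
      # queue until every track is matched, merged, or truly gone.
      r_live <- sqrt(live$area_um2 / pi)
      r_cur <- sqrt(cur$area_um2 / pi)
      queue <- which(!track_used)
      guard <- 0L
      while (length(queue) > 0 && guard < 10L * nrow(live)) {
        guard <- guard + 1L
        ti <- queue[1]
        queue <- queue[-1]
        d2 <- (live$x_um[ti] - cur$x_um)^2 + (live$y_um[ti] - cur$y_um)^2
        gate <- pmax(max_link_distance_um, r_live[ti] + r_cur)
        adm <- which(d2 <= gate^2)
        if (length(adm) == 0) next  # track ends (no successor region)
        ri <- adm[which.min(d2[adm])]
        holder <- which(region_of_track == ri)
        if (length(holder) == 0) {
          # region unclaimed: large-jump continuation of this track
          region_of_track[ti] <- ri
          track_used[ti] <- TRUE
        } else if (live$area_um2[ti] > live$area_um2[holder]) {
          # larger track takes the region; the displaced one re-queues and
          # will record a merge when it loses the rematch
          region_of_track[holder] <- NA_integer_
          track_used[holder] <- FALSE
          region_of_track[ti] <- ri
          track_used[ti] <- TRUE
          queue <- c(queue, holder)
        } else {
          merges <- dplyr::bind_rows(merges, tibble::tibble(
            track_id = live$track_id[ti],
            merged_into = live$track_id[holder],
            merge_time_min = t
          ))
          track_used[ti] <- TRUE
        }
      }
      ok <- which(!is.na(region_of_track))
      assigned_track[region_of_track[ok]] <- live$track_id[ok]
    }
    new_idx <- which(is.na(assigned_track))
    if (length(new_idx) > 0) {
      ids <- seq.int(next_id, length.out = length(new_idx))
      assigned_track[new_idx] <- ids
      next_id <- next_id + length(new_idx)
      births <- dplyr::bind_rows(births, tibble::tibble(
        track_id = ids, birth_time_min = t
      ))
    }
    obs[[length(obs) + 1]] <- tibble::tibble(
      track_id = assigned_track,
      timepoint_min = t,
      label = cur$label, x_um = cur$x_um, y_um = cur$y_um,
      area_um2 = cur$area_um2,
      equivalent_diameter_um = cur$equivalent_diameter_um,
      counted = cur$counted
    )
    live <- tibble::tibble(
      track_id = assigned_track, x_um = cur$x_um, y_um = cur$y_um,
      area_um2 = cur$area_um2
    )
  }
  out <- dplyr::arrange(dplyr::bind_rows(obs), .data$track_id,
                        .data$timepoint_min)
  attr(out, "merges") <- merges
  attr(out, "births") <- births
  class(out) <- c("colony_tracks", class(out))
  out
}

#' Size distribution of counted colonies at a timepoint
#'
#' Sample mean and sample standard deviation (n - 1 denominator) of the
#' equivalent diameters of counted regions at time `t_min`.
#'
#' @param tracks A `colony_tracks` tibble (or any tibble with
#'   `timepoint_min`, `equivalent_diameter_um`, `counted`).
#' @param t_min The timepoint to summarize.
#' @return A tibble: `timepoint_min`, `mean_diameter_um`, `sd_diameter_um`,
#'   `n`, `flag` (`"ok"`, `"n=1"` — SD reported as 0 — or `"empty"`).
#' @export
size_distribution <- function(tracks, t_min) {
  d <- tracks$equivalent_diameter_um[
    tracks$timepoint_min == t_min & tracks$counted
  ]
  n <- length(d)
  tibble::tibble(
    timepoint_min = t_min,
    mean_diameter_um = if (n > 0) mean(d) else NA_real_,
    sd_diameter_um = if (n > 1) stats::sd(d) else if (n == 1) 0 else NA_real_,
    n = n,
    flag = if (n == 0) "empty" else if (n == 1) "n=1" else "ok"
  )
}

#' Count saturation time
#'
#' The earliest timepoint at which the running colony count reaches
#' `fraction` of the final observed count. Microcolony counts rise rapidly
#' once colonies cross the detectability threshold and then plateau; the
#' plateau onset is the practical assay readout time.
#'
#' @param counts Integer vector of counts per timepoint.
#' @param t_min Numeric vector of timepoints (same length).
#' @param fraction Saturation fraction (default 0.95).
#' @return The saturation time in minutes, or `NA` (with a warning) if all
#'   counts are zero.
#' @examples
#' saturation_time(c(0, 0, 10, 48, 50, 50), c(0, 120, 240, 360, 480, 600))
#' @export
saturation_time <- function(counts, t_min, fraction = 0.95) {
  stopifnot(length(counts) == length(t_min), length(counts) >= 1,
            fraction > 0, fraction <= 1)
  final <- counts[length(counts)]
  if (all(counts == 0)) {
    warning("all counts are zero; saturation time undefined")
    return(NA_real_)
  }
  t_min[which(counts >= fraction * final)[1]]
}

#' Titer from a final microcolony count
#'
#' `titer = count * dilution_factor / volume_mL`. The inoculum volume and
#' dilution are explicit inputs: converting an on-sensor count into CFU/mL
#' requires knowing how much diluted suspension the counted area received.
#'
#' @param final_count Colony count (>= 0).
#' @param sample_volume_ul Plated volume, microlitres (> 0).
#' @param dilution_factor Fold dilution of the suspension (>= 1).
#' @return Titer, CFU/mL.
#' @examples
#' estimate_titer(50, 1, 100)  # 5e6 CFU/mL
#' @export
estimate_titer <- function(final_count, sample_volume_ul, dilution_factor = 1) {
  if (sample_volume_ul <= 0) stop("sample volume must be positive")
  if (dilution_factor < 1) stop("dilution factor must be >= 1")
  if (final_count < 0) stop("count must be non-negative")
  final_count * dilution_factor / (sample_volume_ul / 1e3)
}

#' Density bound scaled to a smaller detectable colony size
#'
#' Plate-counting guidance caps colony density to avoid mergers; the cap is
#' inversely proportional to colony footprint area. Scaling a base density
#' quoted at one detectable diameter to another:
#' `bound = base_density * (base_diameter / target_diameter)^2`. With the
#' conventional 10 CFU/cm^2 at 1-mm colonies, 20-um microcolonies admit
#' 25,000 CFU/cm^2.
#'
#' @param base_density_cfu_cm2 Density bound at the base diameter.
#' @param base_diameter_um Diameter the base bound assumes, um.
#' @param target_diameter_um Detectable diameter of interest, um.
#' @return Scaled density bound, CFU/cm^2.
#' @examples
#' density_scale_bound(10, 1000, 20)  # 25000
#' @export
density_scale_bound <- function(base_density_cfu_cm2, base_diameter_um,
                                target_diameter_um) {
  if (base_density_cfu_cm2 <= 0 || base_diameter_um <= 0 ||
      target_diameter_um <= 0) {
    stop("all arguments must be positive")
  }
  base_density_cfu_cm2 * (base_diameter_um / target_diameter_um)^2
}

#' Time-series report: counts, sizes, saturation, titer
#'
#' Aggregates tracked (or raw per-timepoint) regions into the assay's
#' headline outputs: count of colonies at or above the reliability cutoff
#' per timepoint, mean and SD of their equivalent diameters, the 95%
#' saturation time, the final count, the on-sensor density, and a titer
#' estimate if volume/dilution are supplied.
#'
#' @param tracks A `colony_tracks` or `colony_regions` tibble spanning
#'   timepoints.
#' @param sensor A [sensor_spec()] (for the density denominator).
#' @param sample_volume_ul,dilution_factor Optional titer inputs.
#' @param saturation_fraction Fraction for [saturation_time()].
#' @return A list of class `timeseries_report`: `per_timepoint` (tibble:
#'   `timepoint_min`, `count`, `mean_diameter_um`, `sd_diameter_um`, `n`),
#'   `saturation_time_min`, `final_count`, `density_cfu_cm2`,
#'   `titer_cfu_ml` (NA unless volume given).
#' @export
timeseries_report <- function(tracks, sensor, sample_volume_ul = NULL,
                              dilution_factor = 1,
                              saturation_fraction = 0.95) {
  times <- sort(unique(tracks$timepoint_min))
  per <- purrr::map_dfr(times, function(t) {
    sd_row <- size_distribution(tracks, t)
    tibble::tibble(
      timepoint_min = t,
      count = sum(tracks$counted[tracks$timepoint_min == t]),
      mean_diameter_um = sd_row$mean_diameter_um,
      sd_diameter_um = sd_row$sd_diameter_um,
      n = sd_row$n
    )
  })
  final_count <- per$count[nrow(per)]
  sat <- if (all(per$count == 0)) NA_real_ else {
    saturation_time(per$count, per$timepoint_min, saturation_fraction)
  }
  area_cm2 <- sensor_fov_area_mm2(sensor) / 100
  titer <- if (!is.null(sample_volume_ul)) {
    estimate_titer(final_count, sample_volume_ul, dilution_factor)
  } else NA_real_
  structure(
    list(per_timepoint = per, saturation_time_min = sat,
         final_count = final_count,
         density_cfu_cm2 = final_count / area_cm2,
         titer_cfu_ml = titer),
    class = "timeseries_report"
  )
}

#' @export
print.timeseries_report <- function(x, ...) {
  cat(sprintf(
    "<timeseries_report> %d timepoints; final count %d (%.1f CFU/cm^2)\n",
    nrow(x$per_timepoint), x$final_count, x$density_cfu_cm2
  ))
  cat(sprintf("  saturation (95%% of final): %g min; titer: %s CFU/mL\n",
              x$saturation_time_min,
              format(x$titer_cfu_ml, digits = 3)))
  invisible(x)
}

#' Per-track radial growth-rate fits
#'
#' Regresses equivalent diameter on time for each track (least squares over
#' the timepoints where the colony is counted) and reports the radial rate
#' `v = slope / 2` in um/min, recovering the growth-law parameter from the
#' tracked sizes.
#'
#' @param tracks A `colony_tracks` tibble.
#' @param min_points Minimum counted observations required per track.
#' @return A tibble: `track_id`, `n_obs`, `rate_um_min`, `intercept_um`.
#' @export
track_growth_rates <- function(tracks, min_points = 4) {
  tracks |>
    dplyr::filter(.data$counted) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::filter(dplyr::n() >= min_points) |>
    dplyr::summarise(
      n_obs = dplyr::n(),
      rate_um_min = stats::coef(stats::lm(
        equivalent_diameter_um ~ timepoint_min
      ))[2] / 2,
      intercept_um = stats::coef(stats::lm(
        equivalent_diameter_um ~ timepoint_min
      ))[1],
      .groups = "drop"
    )
}
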