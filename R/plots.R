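#' Plot a focus profile
#'
#' Sharpness score against candidate reconstruction depth, with the chosen
#' depth marked.
#'
#' @param object A `focus_profile` tibble from [autofocus()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot focus_profile
#' @export
autoplot.focus_profile <- function(object, ...) {
  best <- attr(object, "best_z_um")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z_um, y = .data$sharpness)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = best, linetype = "dashed") +
    ggplot2::labs(x = "reconstruction depth z (µm)",
                  y = "Tenengrad sharpness",
                  title = sprintf("Digital refocusing (best z = %g µm)", best)) +
    ggplot2::theme_minimal()
}

#' Plot the count-vs-time curve of a report
#'
#' Colony count (at or above the reliability cutoff) per timepoint, with
#' the saturation time marked.
#'
#' @param object A `timeseries_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot timeseries_report
#' @export
autoplot.timeseries_report <- function(object, ...) {
  per <- object$per_timepoint
  p <- ggplot2::ggplot(per, ggplot2::aes(x = .data$timepoint_min,
                                         y = .data$count)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "incubation time (min)",
                  y = "colonies ≥ cutoff diameter",
                  title = "Microcolony count vs incubation time") +
    ggplot2::theme_minimal()
  if (is.finite(object$saturation_time_min)) {
    p <- p + ggplot2::geom_vline(xintercept = object$saturation_time_min,
                                 linetype = "dashed")
  }
  p
}

#' Plot the size distribution over time
#'
#' Mean equivalent diameter with an SD ribbon across timepoints.
#'
#' @param report A `timeseries_report`.
#' @return A ggplot.
#' @export
plot_size_distribution <- function(report) {
  per <- dplyr::filter(report$per_timepoint, .data$n > 0)
  ggplot2::ggplot(per, ggplot2::aes(x = .data$timepoint_min,
                                    y = .data$mean_diameter_um)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_diameter_um - .data$sd_diameter_um,
      ymax = .data$mean_diameter_um + .data$sd_diameter_um
    ), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "incubation time (min)",
                  y = "equivalent diameter (µm)",
                  title = "Microcolony size distribution vs incubation time") +
    ggplot2::theme_minimal()
}

#' Plot colony tracks
#'
#' Equivalent-diameter trajectory of every track; merged tracks end at
#' their merge time.
#'
#' @param object A `colony_tracks` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot colony_tracks
#' @export
autoplot.colony_tracks <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$timepoint_min,
                                       y = .data$equivalent_diameter_um,
                                       group = .data$track_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "incubation time (min)",
                  y = "equivalent diameter (µm)",
                  title = "Per-colony growth trajectories") +
    ggplot2::theme_minimal()
}

#' Plot segmented regions over the field of view
#'
#' Centroid map with circles at each region's equivalent diameter; counted
#' and sub-threshold regions distinguished.
#'
#' @param object A `colony_regions` tibble (one timepoint is clearest).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot colony_regions
#' @export
autoplot.colony_regions <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x_um, y = .data$y_um)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$equivalent_diameter_um,
                                     colour = .data$counted),
                        shape = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  size = "equiv. diameter (µm)", colour = "counted",
                  title = "Segmented microcolonies") +
    ggplot2::theme_minimal()
}

#' Save a QC overlay of the segmentation as PNG
#'
#' Writes the HR image in grayscale with counted regions outlined by their
#' bounding boxes.
#'
#' @param image The segmented [hr_image()].
#' @param regions The matching `colony_regions`.
#' @param path PNG output path.
#' @return `path`, invisibly.
#' @export
write_qc_overlay <- function(image, regions, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for QC overlays")
  }
  m <- strip_image(image)
  m <- (m - min(m)) / max(max(m) - min(m), .Machine$double.eps)
  rgb <- array(rep(m, 3), dim = c(dim(m), 3))
  pitch <- attr(image, "hr_pitch_um")
  for (k in seq_len(nrow(regions))) {
    r <- regions[k, ]
    r1 <- max(1, round(r$bbox_y_um / pitch)); r2 <- min(nrow(m), round((r$bbox_y_um + r$bbox_h_um) / pitch))
    c1 <- max(1, round(r$bbox_x_um / pitch)); c2 <- min(ncol(m), round((r$bbox_x_um + r$bbox_w_um) / pitch))
    col3 <- if (isTRUE(r$counted)) c(0, 1, 0) else c(1, 0.6, 0)
    for (ch in 1:3) {
      rgb[r1:r2, c(c1, c2), ch] <- col3[ch]
      rgb[c(r1, r2), c1:c2, ch] <- col3[ch]
    }
  }
  png::writePNG(rgb, path)
  invisible(path)
}
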