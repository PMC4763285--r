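#' Segmentation parameters
#'
#' Controls for the edge-detection colony segmentation pipeline. All length
#' scales are physical (micrometres) so results do not depend on the
#' enhancement factor; they are converted to pixels using the image's pitch.
#'
#' @param background_correction Divide out the low-frequency illumination
#'   profile before edge detection (default TRUE).
#' @param background_scale_um Smoothing scale of the background estimate;
#'   keep much larger than the largest colony (default 200).
#' @param gradient_threshold `"otsu"` (threshold the Sobel gradient
#'   magnitude by Otsu's method) or a fixed numeric threshold on the
#'   gradient image.
#' @param closing_radius_um Radius of the morphological closing disk
#'   (default 2).
#' @param min_region_area_um2 Discard components smaller than this
#'   (default 20).
#' @param min_diameter_um Reliability cutoff: only regions with equivalent
#'   diameter at or above this are counted (default 20 — smaller
#'   microcolonies are detectable but not reliably enumerable).
#' @param border_policy `"flag"` (regions touching the FOV edge are
#'   reported and counted, with `touches_border = TRUE`) or `"exclude"`
#'   (reported but never counted). Excluding would bias counts on a small
#'   FOV, so flagging is the default.
#' @param refine_with_intensity After edge detection, refine each region's
#'   footprint by thresholding the background-corrected intensity at the
#'   half-depth level inside its bounding box (default TRUE). The gradient
#'   band straddles the colony edge; the intensity half-depth contour tracks
#'   the mid-edge radius, which is what the equivalent diameter should
#'   measure.
#' @param dark_threshold Relative intensity below which pixels are treated
#'   as colony interior and unioned with the edge mask (default 0.8 of the
#'   corrected background). Edge detection alone cannot close the contour
#'   of a colony clipped by the FOV border, so hole filling would leave its
#'   interior unfilled; the absorption mask makes segmentation robust to
#'   that. Set to 0 to disable.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(background_correction = TRUE,
                                background_scale_um = 200,
                                gradient_threshold = "otsu",
                                closing_radius_um = 2,
                                min_region_area_um2 = 20,
                                min_diameter_um = 20,
                                border_policy = c("flag", "exclude"),
                                refine_with_intensity = TRUE,
                                dark_threshold = 0.8) {
  border_policy <- match.arg(border_policy)
  stopifnot(min_diameter_um > 0, closing_radius_um >= 0,
            min_region_area_um2 >= 0, background_scale_um > 0)
  if (!identical(gradient_threshold, "otsu")) {
    stopifnot(is.numeric(gradient_threshold), gradient_threshold > 0)
  }
  structure(
    list(background_correction = background_correction,
         background_scale_um = background_scale_um,
         gradient_threshold = gradient_threshold,
         closing_radius_um = closing_radius_um,
         min_region_area_um2 = min_region_area_um2,
         min_diameter_um = min_diameter_um,
         border_policy = border_policy,
         refine_with_intensity = refine_with_intensity,
         dark_threshold = dark_threshold),
    class = "segmentation_params"
  )
}

#' Flat-field / background correction
#'
#' Divides the image by a smooth estimate of its illumination background:
#' block medians on a grid of cells about `scale_um / 2` wide (the median
#' is robust to colonies occupying part of a cell) are fitted with a
#' quadratic surface, dropping cells the first fit marks as dark outliers
#' (cells dominated by a colony). Low-order illumination structure is
#' removed essentially exactly while colony-scale contrast is untouched;
#' output background is approximately 1.
#'
#' @param image An [hr_image()] (or matrix with `hr_pitch_um` attribute).
#' @param scale_um Background cell scale, micrometres; keep much larger
#'   than the largest colony.
#' @return The corrected image, same class and attributes.
#' @export
correct_background <- function(image, scale_um = 200) {
  pitch <- attr(image, "hr_pitch_um")
  stopifnot(!is.null(pitch), is.finite(pitch), scale_um > 0)
  m <- strip_image(image)
  bg <- estimate_background(m, scale_um / pitch)
  if (any(bg <= 0)) stop("estimated background is non-positive; cannot divide")
  out <- m / bg
  attributes(out) <- attributes(image)
  out
}

# smooth background surface: median per grid cell, trimmed quadratic fit
estimate_background <- function(m, scale_px) {
  ny <- nrow(m); nx <- ncol(m)
  if (min(ny, nx) < 16) {
    return(matrix(stats::median(m), ny, nx))
  }
  cell <- max(8, round(scale_px / 2))
  nby <- max(4, ceiling(ny / cell))
  nbx <- max(4, ceiling(nx / cell))
  ye <- round(seq(0, ny, length.out = nby + 1))
  xe <- round(seq(0, nx, length.out = nbx + 1))
  cells <- tidyr::crossing(iy = seq_len(nby), ix = seq_len(nbx))
  med <- purrr::map2_dbl(cells$iy, cells$ix, function(iy, ix) {
    stats::median(m[(ye[iy] + 1):ye[iy + 1], (xe[ix] + 1):xe[ix + 1]])
  })
  # cell-centre coordinates normalized to [-1, 1]
  cy <- ((ye[-1] + ye[-(nby + 1)] + 1) / 2)[cells$iy] / ny * 2 - 1
  cx <- ((xe[-1] + xe[-(nbx + 1)] + 1) / 2)[cells$ix] / nx * 2 - 1
  fit_once <- function(keep) {
    stats::lm(med ~ cx + cy + I(cx^2) + I(cy^2) + I(cx * cy),
              subset = keep)
  }
  fit <- fit_once(rep(TRUE, length(med)))
  resid <- med - stats::predict(fit, newdata = data.frame(cx = cx, cy = cy))
  sigma <- stats::mad(resid)
  # drop cells darker than the surface (colony-dominated), refit
  keep <- resid > -3 * max(sigma, 1e-12)
  if (any(!keep) && sum(keep) >= 8) fit <- fit_once(keep)
  gy <- seq_len(ny) / ny * 2 - 1
  gx <- seq_len(nx) / nx * 2 - 1
  co <- stats::coef(fit)
  outer(gy, gx, function(y, x) {
    co[1] + co[2] * x + co[3] * y + co[4] * x^2 + co[5] * y^2 + co[6] * x * y
  })
}

strip_image <- function(image) {
  m <- unclass(image)
  attributes(m) <- list(dim = dim(m))
  m
}

#' Equivalent diameter of a region
#'
#' Diameter of the circle whose area equals the region area:
#' `d = 2 * sqrt(area / pi)`.
#'
#' @param area_um2 Region area(s), square micrometres (> 0).
#' @return Equivalent diameter(s), micrometres.
#' @examples
#' equivalent_diameter(pi * 10^2)  # 20
#' @export
equivalent_diameter <- function(area_um2) {
  if (any(area_um2 <= 0)) stop("area must be positive")
  2 * sqrt(area_um2 / pi)
}

#' Segment colonies in a high-resolution image
#'
#' Edge-detection segmentation: optional background correction, Sobel
#' gradient magnitude, threshold (Otsu on the gradient image by default),
#' morphological closing, hole filling, small-object removal, and
#' 8-connected labelling. Each labelled component is measured (area,
#' centroid, bounding box, equivalent diameter) and flagged as counted when
#' its equivalent diameter reaches the reliability cutoff and the border
#' policy allows it.
#'
#' @param image An [hr_image()] (needs a finite `hr_pitch_um`).
#' @param params A [segmentation_params()].
#' @return A tibble of class `colony_regions`, one row per region, sorted by
#'   label: `label`, `area_um2`, `equivalent_diameter_um`, `x_um`, `y_um`,
#'   `bbox_x_um`, `bbox_y_um`, `bbox_w_um`, `bbox_h_um`, `touches_border`,
#'   `counted`, `timepoint_min`. Empty tibble when nothing is found.
#' @export
segment_colonies <- function(image, params = segmentation_params()) {
  pitch <- attr(image, "hr_pitch_um")
  stopifnot(!is.null(pitch), is.finite(pitch))
  m <- strip_image(image)
  if (anyNA(m) || !all(is.finite(m))) stop("image contains non-finite values")
  t_min <- attr(image, "timestamp_min") %||% NA_real_
  if (params$background_correction) {
    bg <- estimate_background(m, params$background_scale_um / pitch)
    if (any(bg <= 0)) stop("estimated background is non-positive")
    m <- m / bg
  } else {
    # normalize to a ~1 background so fixed thresholds are scale-free
    med <- stats::median(m)
    if (med > 0) m <- m / med
  }
  sob <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- eb_filter2(m, sob)
  gy <- eb_filter2(m, t(sob))
  grad <- sqrt(gx^2 + gy^2)
  thr <- if (identical(params$gradient_threshold, "otsu")) {
    # floor at a robust noise level so a featureless frame (where Otsu
    # bisects the noise distribution) yields no regions
    max(otsu_threshold(grad),
        stats::median(grad) + 5 * stats::mad(grad))
  } else {
    params$gradient_threshold
  }
  mask <- grad > thr
  # absorption mask: recovers interiors whose edge contour is clipped at
  # the FOV border (hole filling cannot close those)
  if (params$dark_threshold > 0) {
    mask <- mask | (m < params$dark_threshold)
  }
  r_px <- round(params$closing_radius_um / pitch)
  if (r_px >= 1) {
    brush <- EBImage::makeBrush(2 * r_px + 1, shape = "disc")
    mask <- eb_closing(mask, brush)
  }
  mask <- eb_fill_hull(mask)
  lab <- eb_bwlabel(mask)
  regions <- measure_labels(lab, pitch)
  if (nrow(regions) > 0 && params$refine_with_intensity) {
    regions <- refine_regions(m, lab, regions, pitch)
  }
  if (nrow(regions) > 0) {
    min_area <- max(params$min_region_area_um2, 1e-12)
    regions <- dplyr::filter(regions, .data$area_um2 >= min_area)
    regions$label <- seq_len(nrow(regions))
  }
  fov_w <- ncol(m) * pitch
  fov_h <- nrow(m) * pitch
  regions <- dplyr::mutate(
    regions,
    equivalent_diameter_um = ifelse(.data$area_um2 > 0,
                                    2 * sqrt(.data$area_um2 / pi), 0),
    touches_border = .data$bbox_x_um <= pitch | .data$bbox_y_um <= pitch |
      .data$bbox_x_um + .data$bbox_w_um >= fov_w - pitch |
      .data$bbox_y_um + .data$bbox_h_um >= fov_h - pitch,
    counted = .data$equivalent_diameter_um >= params$min_diameter_um &
      !(params$border_policy == "exclude" & .data$touches_border),
    timepoint_min = t_min
  )
  class(regions) <- c("colony_regions", class(regions))
  regions
}

# Otsu's threshold on a continuous-valued image via a 512-bin histogram
otsu_threshold <- function(x, n_bins = 512L) {
  rng <- range(x)
  if (diff(rng) <= 0) return(rng[1] + 1)  # flat image: nothing above
  h <- graphics::hist(x, breaks = seq(rng[1], rng[2], length.out = n_bins + 1),
                      plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# per-label measurements from an integer label matrix
measure_labels <- function(lab, pitch) {
  idx <- which(lab > 0)
  if (length(idx) == 0) {
    return(tibble::tibble(
      label = integer(), area_um2 = numeric(), x_um = numeric(),
      y_um = numeric(), bbox_x_um = numeric(), bbox_y_um = numeric(),
      bbox_w_um = numeric(), bbox_h_um = numeric()
    ))
  }
  l <- lab[idx]
  ny <- nrow(lab)
  rows <- ((idx - 1) %% ny) + 1
  cols <- ((idx - 1) %/% ny) + 1
  area_px <- tabulate(l)
  labels <- which(area_px > 0)
  sp2 <- pitch^2
  tibble::tibble(
    label = labels,
    area_um2 = area_px[labels] * sp2,
    x_um = unname(vapply(split(cols, l), mean, numeric(1)) - 0.5) * pitch,
    y_um = unname(vapply(split(rows, l), mean, numeric(1)) - 0.5) * pitch,
    bbox_x_um = unname(vapply(split(cols, l), min, numeric(1)) - 1) * pitch,
    bbox_y_um = unname(vapply(split(rows, l), min, numeric(1)) - 1) * pitch,
    bbox_w_um = unname(vapply(split(cols, l), max, numeric(1)) -
                         vapply(split(cols, l), min, numeric(1)) + 1) * pitch,
    bbox_h_um = unname(vapply(split(rows, l), max, numeric(1)) -
                         vapply(split(rows, l), min, numeric(1)) + 1) * pitch
  )
}

# re-measure each region from the intensity half-depth contour inside a
# padded bounding box: the edge-gradient band straddles the colony rim, so
# its outer boundary overestimates the diameter by about the edge width;
# thresholding intensity midway between local background and the region's
# dark level recovers the mid-edge footprint
refine_regions <- function(m, lab, regions, pitch) {
  ny <- nrow(m); nx <- ncol(m)
  pad <- max(2L, round(4 / pitch))
  for (k in seq_len(nrow(regions))) {
    r <- regions[k, ]
    r1 <- max(1L, floor(r$bbox_y_um / pitch) - pad)
    r2 <- min(ny, ceiling((r$bbox_y_um + r$bbox_h_um) / pitch) + pad)
    c1 <- max(1L, floor(r$bbox_x_um / pitch) - pad)
    c2 <- min(nx, ceiling((r$bbox_x_um + r$bbox_w_um) / pitch) + pad)
    sub <- m[r1:r2, c1:c2, drop = FALSE]
    sub_lab <- lab[r1:r2, c1:c2, drop = FALSE]
    inside <- sub_lab == r$label
    if (!any(inside)) next
    dark <- stats::quantile(sub[inside], 0.1, names = FALSE)
    bg <- stats::median(sub[sub_lab == 0])
    if (!is.finite(bg) || bg <= dark) next
    half <- (dark + bg) / 2
    # restrict to this label's neighbourhood so adjacent regions in the
    # same bbox are not absorbed
    cand <- sub < half & (inside | sub_lab == 0)
    cand_lab <- eb_bwlabel(cand)
    keep <- unique(cand_lab[inside & cand])
    keep <- keep[keep > 0]
    if (length(keep) == 0) next
    sel <- matrix(cand_lab %in% keep, nrow(cand_lab))
    n_px <- sum(sel)
    if (n_px == 0) next
    rows <- row(sel)[sel]; cols <- col(sel)[sel]
    regions$area_um2[k] <- n_px * pitch^2
    regions$x_um[k] <- (mean(cols) + c1 - 1 - 0.5) * pitch
    regions$y_um[k] <- (mean(rows) + r1 - 1 - 0.5) * pitch
    regions$bbox_x_um[k] <- (min(cols) + c1 - 2) * pitch
    regions$bbox_y_um[k] <- (min(rows) + r1 - 2) * pitch
    regions$bbox_w_um[k] <- (diff(range(cols)) + 1) * pitch
    regions$bbox_h_um[k] <- (diff(range(rows)) + 1) * pitch
  }
  regions
}

#' Count the reliably enumerable colonies
#'
#' @param regions A `colony_regions` tibble from [segment_colonies()].
#' @return Number of regions with `counted = TRUE`.
#' @export
count_colonies <- function(regions) {
  if (nrow(regions) == 0) return(0L)
  sum(regions$counted)
}
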