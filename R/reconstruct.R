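#' High-resolution image container
#'
#' A reconstruction on an `E`-times finer grid than the sensor. Stored as a
#' plain numeric matrix (rows = y, cols = x) carrying its pixel pitch, the
#' enhancement factor, the focal depth it was reconstructed at, and the
#' acquisition timestamp as attributes.
#'
#' @param m Numeric matrix.
#' @param enhancement_E Integer enhancement factor.
#' @param hr_pitch_um Grid pitch, um (`pixel_pitch / E`).
#' @param focal_z_um Reconstruction depth, um (NA if not applicable).
#' @param timestamp_min Acquisition time, minutes (NA if unknown).
#' @return An object of class `hr_image`.
#' @export
hr_image <- function(m, enhancement_E, hr_pitch_um, focal_z_um = NA_real_,
                     timestamp_min = NA_real_) {
  structure(m, enhancement_E = as.integer(enhancement_E),
            hr_pitch_um = hr_pitch_um, focal_z_um = focal_z_um,
            timestamp_min = timestamp_min,
            class = c("hr_image", "matrix", "array"))
}

#' @export
print.hr_image <- function(x, ...) {
  cat(sprintf(
    "<hr_image> %d x %d px @ %.4g um (E = %d, focal z = %g um, t = %g min)\n",
    ncol(x), nrow(x), attr(x, "hr_pitch_um"), attr(x, "enhancement_E"),
    attr(x, "focal_z_um"), attr(x, "timestamp_min")
  ))
  invisible(x)
}

#' Shift-and-add pixel super-resolution
#'
#' The core reconstruction: each LR frame is deposited onto an accumulation
#' grid `E` times finer than the sensor, displaced by minus its shadow shift
#' (de-shifting the shadow back to its on-axis position) and rounded to the
#' nearest HR bin; a parallel hit-count grid tracks coverage. The output is
#' accumulation / hits where hits > 0; HR bins never visited by any frame
#' are filled by interpolation from their filled neighbours. Because the
#' shift is global, each frame lands on a regular HR sub-lattice and a
#' designed sweep covers all `E^2` sub-pixel phases.
#'
#' With `E = 1` and all-zero shifts this reduces exactly to the arithmetic
#' mean of the frames.
#'
#' @param stack A [frame_stack()] (or plain list of LR matrices).
#' @param shifts A tibble/data.frame with columns `dx`, `dy` (LR pixel
#'   units), one row per frame — typically [schedule_shifts()] output.
#' @param enhancement_E Integer E >= 1.
#' @return An [hr_image()] of dimension `E * dim(LR)` on the intensity scale
#'   of the input frames.
#' @export
shift_and_add <- function(stack, shifts, enhancement_E) {
  frames <- if (inherits(stack, "frame_stack")) stack$frames else stack
  E <- as.integer(enhancement_E)
  stopifnot(E >= 1, nrow(shifts) == length(frames))
  d <- dim(frames[[1]])
  ny <- d[1] * E
  nx <- d[2] * E
  acc <- matrix(0, ny, nx)
  hits <- matrix(0L, ny, nx)
  lr_rows <- seq_len(d[1])
  lr_cols <- seq_len(d[2])
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    if (anyNA(fr)) stop("NaN/NA in input frame ", f)
    # LR pixel centre (i - 0.5) LR units, de-shifted, mapped to HR bin index
    ri <- round((lr_rows - 0.5) * E + 0.5 - shifts$dy[f] * E)
    ci <- round((lr_cols - 0.5) * E + 0.5 - shifts$dx[f] * E)
    rok <- ri >= 1 & ri <= ny
    cok <- ci >= 1 & ci <= nx
    if (!any(rok) || !any(cok)) next
    acc[ri[rok], ci[cok]] <- acc[ri[rok], ci[cok]] + fr[lr_rows[rok], lr_cols[cok]]
    hits[ri[rok], ci[cok]] <- hits[ri[rok], ci[cok]] + 1L
  }
  if (all(hits == 0L)) stop("no frame content landed on the HR grid")
  out <- acc
  filled <- hits > 0L
  out[filled] <- acc[filled] / hits[filled]
  out[!filled] <- NA_real_
  if (!all(filled)) out <- fill_holes_interp(out)
  hr_image(out, E, hr_pitch_um = NA_real_,
           timestamp_min = if (inherits(stack, "frame_stack")) {
             stack$timestamp_min
           } else NA_real_)
}

# fill NA bins by separable linear interpolation (rows then columns),
# then nearest-neighbour diffusion for anything still empty (corners)
fill_holes_interp <- function(m) {
  interp_vec <- function(v) {
    ok <- which(!is.na(v))
    if (length(ok) < 2) return(v)
    idx <- which(is.na(v))
    idx <- idx[idx > ok[1] & idx < ok[length(ok)]]
    if (length(idx) > 0) {
      v[idx] <- stats::approx(ok, v[ok], xout = idx)$y
    }
    v
  }
  m <- t(apply(m, 1, interp_vec))
  if (anyNA(m)) m <- apply(m, 2, interp_vec)
  guard <- 0L
  while (anyNA(m) && guard < 1000L) {
    na_idx <- which(is.na(m), arr.ind = TRUE)
    for (k in seq_len(nrow(na_idx))) {
      i <- na_idx[k, 1]; j <- na_idx[k, 2]
      nb <- m[max(1, i - 1):min(nrow(m), i + 1),
              max(1, j - 1):min(ncol(m), j + 1)]
      if (!all(is.na(nb))) m[i, j] <- mean(nb, na.rm = TRUE)
    }
    guard <- guard + 1L
  }
  m
}

#' Reconstruct an HR image at an assumed depth
#'
#' Composition of [schedule_shifts()] at depth `z_um` and
#' [shift_and_add()]; the output records `z_um` as its focal depth. Choosing
#' different depths changes the de-shifts applied to the frames, which is
#' what makes digital refocusing possible after acquisition.
#'
#' @param stack A [frame_stack()].
#' @param sensor A [sensor_spec()].
#' @param z_um Assumed sample height, um.
#' @param enhancement_E Integer E.
#' @param schedule Scan schedule; defaults to the one stored in the stack.
#' @return An [hr_image()].
#' @export
reconstruct_at <- function(stack, sensor, z_um, enhancement_E,
                           schedule = stack$schedule) {
  shifts <- schedule_shifts(schedule, z_um, sensor)
  out <- shift_and_add(stack, shifts, enhancement_E)
  attr(out, "hr_pitch_um") <- sensor$pixel_pitch_um / enhancement_E
  attr(out, "focal_z_um") <- z_um
  out
}

#' Tenengrad sharpness score
#'
#' Mean squared gradient magnitude over a region of interest, using 3x3
#' Sobel kernels. Non-negative, zero for a constant image, and invariant to
#' additive intensity offsets — the focus criterion used to pick the
#' reconstruction depth at which colony boundaries are crisp.
#'
#' @param image Numeric matrix (e.g. an [hr_image()]).
#' @param roi Optional integer vector `c(row1, row2, col1, col2)` selecting
#'   a sub-rectangle; default scores the whole image.
#' @param presmooth_sigma_px Gaussian pre-smoothing applied before the
#'   gradient (0 = none). Shift-and-add at a wrong depth produces
#'   bin-to-bin misregistration speckle whose gradients can outscore a
#'   genuinely focused edge; smoothing by about the HR point-spread scale
#'   suppresses the speckle while keeping the edge contrast ordering.
#' @return A single non-negative score.
#' @export
compute_sharpness <- function(image, roi = NULL, presmooth_sigma_px = 0) {
  m <- unclass(image)
  attributes(m) <- list(dim = dim(m))
  if (presmooth_sigma_px > 0) m <- eb_gblur(m, presmooth_sigma_px)
  if (!is.null(roi)) {
    stopifnot(length(roi) == 4)
    if (roi[1] < 1 || roi[3] < 1 || roi[2] > nrow(m) || roi[4] > ncol(m) ||
        roi[1] > roi[2] || roi[3] > roi[4]) {
      stop("roi outside image")
    }
    m <- m[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  }
  sob <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- eb_filter2(m, sob)
  gy <- eb_filter2(m, t(sob))
  mean(gx^2 + gy^2)
}

#' Autofocus: reconstruct across candidate depths and pick the sharpest
#'
#' Reconstructs the stack at every candidate depth, scores each with
#' [compute_sharpness()] and returns the profile plus the best
#' reconstruction. Ties break toward the smaller depth. A warning is raised
#' if the best score sits at an endpoint of the scanned range (the true
#' plane may lie outside it, or the scene is featureless).
#'
#' @param stack A [frame_stack()].
#' @param sensor A [sensor_spec()].
#' @param z_candidates_um Sorted numeric vector of candidate depths (>= 2).
#' @param enhancement_E Integer E.
#' @param roi Optional ROI passed to [compute_sharpness()] for per-colony
#'   local refocusing.
#' @param presmooth_sigma_px Pre-smoothing for the sharpness metric, HR
#'   pixels (default 1.5; see [compute_sharpness()]).
#' @param schedule Scan schedule; defaults to the stack's.
#' @return A list with `profile` (tibble of class `focus_profile`: `z_um`,
#'   `sharpness`), `best_z_um`, and `image` (the reconstruction at the best
#'   depth).
#' @export
autofocus <- function(stack, sensor, z_candidates_um, enhancement_E,
                      roi = NULL, presmooth_sigma_px = 1.5,
                      schedule = stack$schedule) {
  if (length(z_candidates_um) < 2) {
    stop("need at least two candidate depths")
  }
  stopifnot(!is.unsorted(z_candidates_um))
  recs <- purrr::map(z_candidates_um, function(z) {
    reconstruct_at(stack, sensor, z, enhancement_E, schedule)
  })
  scores <- purrr::map_dbl(recs, compute_sharpness, roi = roi,
                           presmooth_sigma_px = presmooth_sigma_px)
  best <- which(scores >= max(scores))[1]  # ties toward smaller z
  if (best == 1 || best == length(scores)) {
    warning("sharpness maximum at an endpoint of the depth range")
  }
  profile <- tibble::tibble(z_um = z_candidates_um, sharpness = scores)
  class(profile) <- c("focus_profile", class(profile))
  attr(profile, "best_z_um") <- z_candidates_um[best]
  list(profile = profile, best_z_um = z_candidates_um[best],
       image = recs[[best]])
}

#' Intensity profile between two points of an image
#'
#' Samples the image by bilinear interpolation along the segment joining two
#' physical points. Used to apply a two-point resolution criterion: a pair
#' counts as resolved when the profile dips by at least the stated fraction
#' between the two intensity minima.
#'
#' @param image An [hr_image()] or plain matrix.
#' @param p1_um,p2_um Physical endpoints `c(x_um, y_um)`.
#' @param pitch_um Grid pitch; defaults to the image's `hr_pitch_um`.
#' @param n Number of samples along the segment.
#' @return A tibble: `s_um` (arc position), `intensity`.
#' @export
profile_between <- function(image, p1_um, p2_um, pitch_um = NULL, n = 101) {
  pitch <- pitch_um %||% attr(image, "hr_pitch_um")
  stopifnot(!is.null(pitch), is.finite(pitch))
  m <- unclass(image)
  tt <- seq(0, 1, length.out = n)
  xs <- (p1_um[1] + tt * (p2_um[1] - p1_um[1])) / pitch + 0.5
  ys <- (p1_um[2] + tt * (p2_um[2] - p1_um[2])) / pitch + 0.5
  x0 <- pmin(pmax(floor(xs), 1), ncol(m) - 1)
  y0 <- pmin(pmax(floor(ys), 1), nrow(m) - 1)
  wx <- pmin(pmax(xs - x0, 0), 1)
  wy <- pmin(pmax(ys - y0, 0), 1)
  val <- m[cbind(y0, x0)] * (1 - wx) * (1 - wy) +
    m[cbind(y0, x0 + 1)] * wx * (1 - wy) +
    m[cbind(y0 + 1, x0)] * (1 - wx) * wy +
    m[cbind(y0 + 1, x0 + 1)] * wx * wy
  tibble::tibble(
    s_um = tt * sqrt(sum((p2_um - p1_um)^2)),
    intensity = val
  )
}

#' Two-point resolution check
#'
#' Given the known positions of two dark points, decides whether the image
#' resolves them: the intensity at the midpoint of the joining segment must
#' rise above the shallower of the two minima by at least `min_dip` of the
#' background-to-minimum depth.
#'
#' @param image An [hr_image()] or matrix with a known pitch.
#' @param p1_um,p2_um The two point positions, `c(x_um, y_um)`.
#' @param background Background intensity level; default: maximum of the
#'   sampled profile extended one separation beyond each point.
#' @param min_dip Required relative dip (default 0.2).
#' @param pitch_um Grid pitch override.
#' @return A list: `resolved` (logical), `dip` (achieved relative dip).
#' @export
resolves_pair <- function(image, p1_um, p2_um, background = NULL,
                          min_dip = 0.2, pitch_um = NULL) {
  sep <- p2_um - p1_um
  pitch <- pitch_um %||% attr(image, "hr_pitch_um")
  # average a few parallel profiles (half a pixel apart, perpendicular to
  # the pair axis) so shot noise on single samples cannot fake a dip
  perp <- c(-sep[2], sep[1]) / sqrt(sum(sep^2))
  profs <- purrr::map((-1):1, function(k) {
    off <- perp * k * pitch / 2
    profile_between(image, p1_um - sep + off, p2_um + sep + off,
                    pitch_um = pitch, n = 301)
  })
  prof <- profs[[1]]
  prof$intensity <- (profs[[1]]$intensity + profs[[2]]$intensity +
                       profs[[3]]$intensity) / 3
  if (is.null(background)) background <- max(prof$intensity)
  s_tot <- max(prof$s_um)
  # the points sit at 1/3 and 2/3 of the extended profile; sample each
  # location as a windowed mean (window-minima would bias the dip upward
  # under shot noise on an unresolved, flat-bottomed profile)
  w <- 0.05 * s_tot
  at <- function(frac) {
    mean(prof$intensity[abs(prof$s_um - frac * s_tot) <= w])
  }
  min1 <- at(1 / 3)
  min2 <- at(2 / 3)
  mid <- at(1 / 2)
  depth <- background - max(min1, min2)
  dip <- if (depth <= 0) 0 else (mid - max(min1, min2)) / depth
  list(resolved = is.finite(dip) && dip >= min_dip, dip = dip)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
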