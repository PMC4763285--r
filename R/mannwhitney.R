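#' Exact Mann-Whitney U test (small samples, ties allowed)
#'
#' Rank-sum comparison of two small groups of titers by full enumeration.
#' The statistic is `U = sum over pairs [a > b] + 0.5 * [a == b]` (group A
#' vs group B). The two-sided p-value is exact: all `choose(nA + nB, nA)`
#' assignments of the pooled values to groups are enumerated and `p` is the
#' fraction of assignments whose U deviates from the null mean
#' `nA * nB / 2` by at least as much as the observed U. Ties are handled
#' exactly by the half-count convention — no normal approximation and no
#' continuity correction, appropriate for the n = 5 per-group comparisons
#' typical of assay validation.
#'
#' @param group_a,group_b Numeric vectors (each non-empty; enumeration is
#'   intended for group sizes up to ~10).
#' @return A list of class `mw_exact`: `statistic` (U for group A), `p_value`
#'   (exact two-sided), `n_a`, `n_b`, `n_assignments`.
#' @examples
#' mann_whitney_exact(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney_exact <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty")
  }
  stopifnot(is.numeric(group_a), is.numeric(group_b),
            all(is.finite(group_a)), all(is.finite(group_b)))
  na <- length(group_a)
  nb <- length(group_b)
  u_stat <- function(a, b) {
    # pairwise comparison with half-credit for ties
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_stat(group_a, group_b)
  pooled <- c(group_a, group_b)
  mu <- na * nb / 2
  dev_obs <- abs(u_obs - mu)
  assignments <- utils::combn(na + nb, na)
  devs <- apply(assignments, 2, function(idx) {
    abs(u_stat(pooled[idx], pooled[-idx]) - mu)
  })
  eps <- 1e-9
  p <- mean(devs >= dev_obs - eps)
  structure(
    list(statistic = u_obs, p_value = p, n_a = na, n_b = nb,
         n_assignments = ncol(assignments)),
    class = "mw_exact"
  )
}

#' @export
print.mw_exact <- function(x, ...) {
  cat(sprintf(
    "Exact Mann-Whitney U test: U = %g, p = %.4g (n = %d vs %d, %d assignments)\n",
    x$statistic, x$p_value, x$n_a, x$n_b, x$n_assignments
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an exact Mann-Whitney result
#'
#' @param x An `mw_exact` object.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `p.value`, `n.a`, `n.b`, `method`.
#' @method tidy mw_exact
#' @export
tidy.mw_exact <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, p.value = x$p_value,
    n.a = x$n_a, n.b = x$n_b,
    method = "Exact Mann-Whitney U (full enumeration)"
  )
}

#' @rdname tidy.mw_exact
#' @method glance mw_exact
#' @export
glance.mw_exact <- function(x, ...) tidy(x)

#' Tidy a time-series report
#'
#' @param x A `timeseries_report`.
#' @param ... Unused.
#' @return The per-timepoint tibble (`timepoint_min`, `count`,
#'   `mean_diameter_um`, `sd_diameter_um`, `n`).
#' @method tidy timeseries_report
#' @export
tidy.timeseries_report <- function(x, ...) x$per_timepoint

#' One-row summary of a time-series report
#'
#' @param x A `timeseries_report`.
#' @param ... Unused.
#' @return One-row tibble: `final_count`, `saturation_time_min`,
#'   `density_cfu_cm2`, `titer_cfu_ml`.
#' @method glance timeseries_report
#' @export
glance.timeseries_report <- function(x, ...) {
  tibble::tibble(
    final_count = x$final_count,
    saturation_time_min = x$saturation_time_min,
    density_cfu_cm2 = x$density_cfu_cm2,
    titer_cfu_ml = x$titer_cfu_ml
  )
}
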