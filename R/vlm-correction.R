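#' Does a site need a differential vertical-land-motion correction?
#'
#' The water-level gauge (shallow anchoring, typically 4-5 m) and the
#' surface-elevation benchmark rod (~20 m) subside differently when either
#' floats in compaction-prone Holocene strata. No correction is needed only
#' when both instruments penetrate the Pleistocene basement, i.e. both
#' installation depths reach the Holocene-Pleistocene interface depth.
#'
#' @param station A one-row data frame (or list) with `rset_depth_m`,
#'   `gauge_depth_m` and `hp_depth_m` resolved (defaults and
#'   nearest-neighbor fills already applied).
#' @return Logical: `TRUE` when a differential correction is required.
#' @export
requires_correction <- function(station) {
  hp <- station$hp_depth_m
  if (is.null(hp) || length(hp) != 1 || is.na(hp)) {
    stop("Holocene-Pleistocene interface depth unresolved for this station")
  }
  !(station$rset_depth_m >= hp && station$gauge_depth_m >= hp)
}

#' Build the differential VLM correction distribution
#'
#' The correction rate is modeled as a normal distribution pinned by its 5th
#' and 95th percentiles (defaults 1 and 4 mm/yr): mean is their midpoint and
#' the standard deviation is `(p95 - p5) / (2 * qnorm(0.95))`.
#'
#' @param p5,p95 Percentile pins in mm/yr, `p5 < p95`.
#' @return Object of class `vlm_model` with `mean_mm_yr`, `sd_mm_yr`,
#'   `p5_mm_yr`, `p95_mm_yr`.
#' @export
vlm_model <- function(p5 = 1, p95 = 4) {
  if (!is.finite(p5) || !is.finite(p95)) stop("percentile pins must be finite")
  if (p5 >= p95) stop("p5 must be strictly below p95")
  structure(
    list(mean_mm_yr = (p5 + p95) / 2,
         sd_mm_yr = (p95 - p5) / (2 * stats::qnorm(0.95)),
         p5_mm_yr = p5, p95_mm_yr = p95),
    class = "vlm_model"
  )
}

#' Draw correction rates for one site
#'
#' Seeded normal draws from the correction model. Sites that do not require
#' a correction receive all-zero draws so the downstream arithmetic is
#' uniform; the exemption is recorded in the returned attribute.
#'
#' @param model A [vlm_model()].
#' @param n_draws Number of draws; default 10000.
#' @param seed Integer seed.
#' @param applicable Logical; `FALSE` returns zeros (exempt site).
#' @return Numeric vector of correction rates in mm/yr with attribute
#'   `applicable`.
#' @export
draw_corrections <- function(model, n_draws = 10000, seed = NULL,
                             applicable = TRUE) {
  stopifnot(inherits(model, "vlm_model"))
  draws <- if (applicable) {
    with_seed(seed, stats::rnorm(n_draws, model$mean_mm_yr, model$sd_mm_yr))
  } else {
    rep(0, n_draws)
  }
  attr(draws, "applicable") <- applicable
  draws
}

#' Subtract VLM correction draws from a water-level trend ensemble
#'
#' Index-paired subtraction: ensemble member i minus correction draw i.
#' Correction draws are sampled independently of the trend ensemble, so the
#' corrected ensemble variance is approximately the sum of the two
#' variances.
#'
#' @param rwl A `trend_ensemble` of relative water-level trends.
#' @param corrections Numeric vector from [draw_corrections()], same length
#'   as the ensemble draws.
#' @return A `trend_ensemble` of corrected (cRWL) trends; the point rate is
#'   reduced by the mean of the corrections actually drawn.
#' @export
correct_trend_ensemble <- function(rwl, corrections) {
  stopifnot(inherits(rwl, "trend_ensemble"))
  if (length(corrections) != length(rwl$draws_mm_yr)) {
    stop("correction draws and ensemble draws differ in length")
  }
  out <- rwl
  out$draws_mm_yr <- rwl$draws_mm_yr - corrections
  out$rate_mm_yr <- rwl$rate_mm_yr - mean(corrections)
  out
}

#' Remove cumulative differential VLM from an elevation series
#'
#' Elevations were surveyed to the geodetic datum in the survey year, so
#' that epoch is the fixed point: `corrected(t) = raw(t) - rate * (t -
#' survey_year)` with `t` in decimal years. Values after the survey are
#' lowered by the accumulated motion and values before it are raised.
#'
#' @param series A [level_series()] (monthly water elevations, typically).
#' @param vlm_rate_mm_yr Correction rate in mm/yr.
#' @param survey_year Calendar year of the geodetic survey; default 2014.
#' @return The corrected [level_series()].
#' @export
correct_elevations <- function(series, vlm_rate_mm_yr, survey_year = 2014) {
  stopifnot(inherits(series, "level_series"))
  t_dec <- decimal_year(series$time)
  out <- series
  out$value <- series$value - (vlm_rate_mm_yr / 1000) * (t_dec - survey_year)
  out
}
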