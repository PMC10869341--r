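#' Average per-location projection curves into one regional curve
#'
#' Sea-level-rise rate projections are provided at several coastal
#' locations on a shared decadal grid; the regional curve is the unweighted
#' mean rate (and mean one-sigma band) per decade, per scenario.
#'
#' @param curves Data frame with columns `scenario`, `location_id`, `year`,
#'   `rate_mm_yr`, `sigma_mm_yr`; all locations of a scenario must share the
#'   decadal grid.
#' @return Data frame with columns `scenario`, `year`, `rate_mm_yr`,
#'   `sigma_mm_yr` (one row per scenario-decade).
#' @export
average_locations <- function(curves) {
  needed <- c("scenario", "location_id", "year", "rate_mm_yr", "sigma_mm_yr")
  if (!all(needed %in% names(curves))) {
    stop("curves must have columns ", paste(needed, collapse = ", "))
  }
  split_sc <- split(curves, curves$scenario)
  out <- lapply(split_sc, function(sc) {
    grids <- split(sc$year, sc$location_id)
    ref <- sort(grids[[1]])
    if (!all(vapply(grids, function(g) identical(sort(g), ref), TRUE))) {
      stop("locations within scenario '", sc$scenario[1],
           "' do not share a decadal grid")
    }
    data.frame(scenario = sc$scenario[1],
               year = ref,
               rate_mm_yr = tapply(sc$rate_mm_yr, sc$year, mean)[as.character(ref)],
               sigma_mm_yr = tapply(sc$sigma_mm_yr, sc$year, mean)[as.character(ref)],
               row.names = NULL)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Convert observed deficits into rise-rate thresholds
#'
#' Subtracting a cross-site surface-elevation-deficit percentile from the
#' observed rate of geocentric sea-level rise gives the rise rate at which
#' the corresponding fraction of sites would be in deficit: e.g. the median
#' deficit yields the rate at which about half the sites fail to keep pace.
#'
#' @param observed_rate_mm_yr Observed geocentric sea-level rise rate.
#' @param deficit_percentiles Named numeric vector of deficit percentiles
#'   in mm/yr (names like `"25%"`, `"50%"`).
#' @return Data frame with `percentile`, `deficit_mm_yr`,
#'   `threshold_mm_yr`, `frac_sites_in_deficit`.
#' @export
thresholds_from_deficits <- function(observed_rate_mm_yr, deficit_percentiles) {
  pct <- names(deficit_percentiles)
  if (is.null(pct)) pct <- rep(NA_character_, length(deficit_percentiles))
  frac <- suppressWarnings(as.numeric(sub("%", "", pct)) / 100)
  data.frame(percentile = pct,
             deficit_mm_yr = unname(deficit_percentiles),
             threshold_mm_yr = observed_rate_mm_yr - unname(deficit_percentiles),
             frac_sites_in_deficit = frac,
             row.names = NULL)
}

#' First decade when a projected rate crosses a threshold
#'
#' Scans the decadal grid in order and reports the first year whose selected
#' rate (central, or central plus one sigma) is at least the threshold; `NA`
#' when the threshold is never reached by the end of the grid. No
#' interpolation between decades: crossings are reported at the grid's
#' native resolution.
#'
#' @param curve One scenario's averaged curve (columns `year`, `rate_mm_yr`,
#'   `sigma_mm_yr`).
#' @param threshold_mm_yr Finite threshold rate.
#' @param band `"central"` or `"upper1sigma"`.
#' @return Integer year, or `NA_integer_`.
#' @export
crossing_year <- function(curve, threshold_mm_yr,
                          band = c("central", "upper1sigma")) {
  band <- match.arg(band)
  if (nrow(curve) == 0) stop("empty projection curve")
  if (!is.finite(threshold_mm_yr)) stop("threshold must be finite")
  o <- order(curve$year)
  rate <- curve$rate_mm_yr[o]
  if (band == "upper1sigma") rate <- rate + curve$sigma_mm_yr[o]
  hit <- which(rate >= threshold_mm_yr)
  if (length(hit) == 0) NA_integer_ else as.integer(curve$year[o][hit[1]])
}

#' Crossing-year table for every scenario and threshold
#'
#' @param curves Averaged curves (from [average_locations()]) covering one
#'   or more scenarios.
#' @param thresholds Data frame from [thresholds_from_deficits()].
#' @param bands Bands to evaluate; default both.
#' @return Data frame with one row per (scenario, threshold, band):
#'   `scenario`, `band`, `percentile`, `threshold_mm_yr`,
#'   `frac_sites_in_deficit`, `crossing_year`.
#' @export
scenario_report <- function(curves, thresholds,
                            bands = c("central", "upper1sigma")) {
  if (nrow(curves) == 0 || nrow(thresholds) == 0) {
    stop("need at least one curve and one threshold")
  }
  rows <- list()
  for (sc in unique(curves$scenario)) {
    curve <- curves[curves$scenario == sc, ]
    for (i in seq_len(nrow(thresholds))) {
      for (b in bands) {
        rows[[length(rows) + 1]] <- data.frame(
          scenario = sc, band = b,
          percentile = thresholds$percentile[i],
          threshold_mm_yr = thresholds$threshold_mm_yr[i],
          frac_sites_in_deficit = thresholds$frac_sites_in_deficit[i],
          crossing_year = crossing_year(curve, thresholds$threshold_mm_yr[i], b))
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
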