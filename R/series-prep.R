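#' Aggregate a level series to a coarser cadence
#'
#' Hourly records are averaged into daily means and daily records into
#' calendar-month means. Each aggregated period carries a completeness
#' fraction: the number of source records present divided by the number
#' expected (24 hours per day; the true day count of each calendar month,
#' leap years included). A period with no source data is kept on the grid
#' with a missing value and completeness 0, so downstream filters see it.
#'
#' @param series A [level_series()].
#' @param target_cadence `"daily"` or `"monthly"`; must be coarser than the
#'   source cadence.
#' @return A [level_series()] at the target cadence with completeness.
#' @export
aggregate_series <- function(series, target_cadence = c("monthly", "daily")) {
  stopifnot(inherits(series, "level_series"))
  target_cadence <- match.arg(target_cadence)
  order_of <- c(hourly = 1L, daily = 2L, monthly = 3L, biannual = 4L)
  if (order_of[[series$cadence]] >= order_of[[target_cadence]]) {
    stop(sprintf("cannot aggregate %s series to %s cadence",
                 series$cadence, target_cadence))
  }
  if (series$cadence == "hourly" && target_cadence == "monthly") {
    return(aggregate_series(aggregate_series(series, "daily"), "monthly"))
  }

  if (target_cadence == "daily") {
    key <- as.Date(series$time, tz = attr(series$time, "tzone") %||% "UTC")
    grid <- seq(min(key), max(key), by = "day")
    expected <- rep(24, length(grid))
  } else {
    key <- month_floor(series$time)
    grid <- month_seq(min(key), max(key))
    expected <- days_in_month(grid)
  }
  present <- !is.na(series$value)
  sums <- vapply(grid, function(g) sum(series$value[present & key == g]), 0)
  counts <- vapply(grid, function(g) sum(present & key == g), 0L)
  value <- ifelse(counts > 0, sums / counts, NA_real_)
  level_series(series$site_id, grid, value, target_cadence,
               completeness = counts / expected)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Drop under-observed months from a monthly series
#'
#' A month is retained only when its daily completeness strictly exceeds the
#' threshold; a month at exactly the threshold is dropped. The grid is
#' preserved — dropped months become missing values with their completeness
#' zeroed, so site-level completeness accounting still sees them.
#'
#' @param series Monthly [level_series()] with completeness.
#' @param threshold Completeness fraction; default 0.70.
#' @return The filtered monthly series.
#' @export
apply_month_completeness <- function(series, threshold = 0.70) {
  stopifnot(inherits(series, "level_series"))
  if (series$cadence != "monthly" || is.null(series$completeness)) {
    stop("requires a monthly series carrying completeness")
  }
  drop <- series$completeness <= threshold
  series$value[drop] <- NA_real_
  series$completeness[drop] <- 0
  series
}

#' Does a site pass the monthly completeness filter?
#'
#' A site is kept when the fraction of observed months over the study window
#' is at least the threshold (sites strictly below it are excluded).
#'
#' @param series Monthly [level_series()].
#' @param threshold Fraction of window months required; default 0.70.
#' @param window Optional `c(start, end)` dates delimiting the study window;
#'   defaults to the span of the series itself.
#' @return Logical scalar.
#' @export
site_passes <- function(series, threshold = 0.70, window = NULL) {
  stopifnot(inherits(series, "level_series"))
  if (series$cadence != "monthly") stop("requires a monthly series")
  if (is.null(window)) {
    months <- month_seq(min(series$time), max(series$time))
  } else {
    months <- month_seq(as.Date(window[1]), as.Date(window[2]))
  }
  if (length(months) == 0) stop("empty study window")
  got <- series$time[!is.na(series$value)]
  sum(months %in% got) / length(months) >= threshold
}

#' Remove the mean seasonal cycle from a monthly series
#'
#' Detrends a copy of the series by ordinary least squares, averages the
#' detrended values over each calendar month to obtain a 12-value
#' climatology (mean-centered), and subtracts that climatology from the raw
#' series. The trend is retained in the output; only the repeating seasonal
#' offsets are removed.
#'
#' @param series Monthly [level_series()] with at least 24 observed months
#'   and every calendar month observed at least twice.
#' @return A list with `series` (the deseasonalized [level_series()]) and
#'   `climatology` (named numeric vector of 12 monthly offsets in meters).
#' @export
deseasonalize <- function(series) {
  stopifnot(inherits(series, "level_series"))
  if (series$cadence != "monthly") stop("requires a monthly series")
  obs <- !is.na(series$value)
  if (sum(obs) < 24) stop("need at least 24 observed months to deseasonalize")
  mon <- as.integer(format(series$time, "%m"))
  tab <- table(factor(mon[obs], levels = 1:12))
  if (any(tab < 2)) {
    bad <- month.abb[which(tab < 2)]
    stop(sprintf("calendar month(s) %s observed fewer than twice",
                 paste(bad, collapse = ", ")))
  }
  resid <- detrend(series)
  clim <- vapply(1:12, function(m) mean(resid$value[obs & mon == m]), 0)
  clim <- clim - mean(clim)
  names(clim) <- month.abb
  out <- series
  out$value <- unname(series$value - clim[mon])
  list(series = out, climatology = clim)
}

#' Residuals of the ordinary-least-squares line through a series
#'
#' Fits elevation against decimal year by OLS on the observed values and
#' returns the residual series (missing stamps stay missing). Time is
#' centered on the series midpoint for conditioning; residuals are invariant
#' to that choice.
#'
#' @param series A [level_series()] with at least 3 observed values.
#' @return A [level_series()] of residuals in meters.
#' @export
detrend <- function(series) {
  stopifnot(inherits(series, "level_series"))
  obs <- !is.na(series$value)
  if (sum(obs) < 3) stop("need at least 3 observed values to detrend")
  t_dec <- decimal_year(series$time)
  tc <- t_dec - mean(t_dec[obs])
  fit <- stats::lm.fit(cbind(1, tc[obs]), series$value[obs])
  out <- series
  out$value[obs] <- fit$residuals
  out
}

#' Summarize the preprocessing of one site's water-level record
#'
#' Runs the standard chain — aggregate to monthly, month-level completeness
#' filter, site-level completeness filter, deseasonalization — and reports
#' what was kept.
#'
#' @param series Daily (or hourly) [level_series()].
#' @param month_threshold Per-month daily completeness threshold (strict).
#' @param site_threshold Site-level monthly completeness threshold.
#' @param window Optional study window passed to [site_passes()].
#' @return A list: `monthly` (filtered monthly series), `deseasonalized`
#'   (or `NULL` when the site fails), `climatology`, `passed`,
#'   `months_kept`, `months_total`.
#' @export
prep_site <- function(series, month_threshold = 0.70, site_threshold = 0.70,
                      window = NULL) {
  monthly <- series
  if (monthly$cadence %in% c("hourly", "daily")) {
    monthly <- aggregate_series(monthly, "monthly")
  }
  monthly <- apply_month_completeness(monthly, month_threshold)
  passed <- site_passes(monthly, site_threshold, window)
  deseas <- NULL
  clim <- NULL
  if (passed) {
    ds <- deseasonalize(monthly)
    deseas <- ds$series
    clim <- ds$climatology
  }
  list(monthly = monthly, deseasonalized = deseas, climatology = clim,
       passed = passed,
       months_kept = sum(!is.na(monthly$value)),
       months_total = length(monthly$time))
}
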