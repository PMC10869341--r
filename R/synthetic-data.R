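#' Configuration of the synthetic monitoring network
#'
#' Defines the statistical structure of a synthetic coastal monitoring
#' network: paired water-level gauges and wetland surface-elevation
#' benchmarks whose series are linear trend + annual seasonal harmonic +
#' shared ocean signal + AR(1) noise (water, daily cadence) and linear
#' trend + white noise (wetland surface, biannual cadence). All elevations
#' are in meters; trends and noise scales are stated in mm/yr and mm.
#'
#' @param n_sites Number of monitoring sites.
#' @param start,end Study window (coerced to `Date`); must span at least 24
#'   months.
#' @param rwl_trend_range Range (mm/yr) of the true gauge-vs-benchmark
#'   corrected water-level trend; the observable relative water-level trend
#'   additionally carries the site's differential vertical-land-motion rate.
#' @param sec_trend_range Range (mm/yr) of true surface-elevation-change
#'   trends.
#' @param seasonal_amplitude Annual harmonic amplitude in mm (site phase
#'   drawn uniformly).
#' @param ar1_phi_range Range of site AR(1) lag-1 coefficients, strictly
#'   inside (-1, 1).
#' @param innovation_sd Monthly AR(1) innovation standard deviation, mm.
#' @param daily_noise_sd Additional independent daily noise, mm.
#' @param shared_signal_weight Loading of the common ocean signal onto each
#'   site, in \[0, 1\].
#' @param shared_phi,shared_innovation_sd AR(1) parameters of the common
#'   monthly ocean signal (mm).
#' @param sec_noise_sd White-noise standard deviation of biannual
#'   surface-elevation measurements, mm.
#' @param sec_missingness_rate Fraction of biannual occasions dropped.
#' @param gauge_depth_range Gauge installation depth range, m.
#' @param rset_depth_default Benchmark rod installation depth, m.
#' @param hp_depth_range Holocene-Pleistocene interface depth range, m.
#' @param tidal_amplitude_range Annual tidal amplitude range, m.
#' @param organic_fraction_range Soil organic-matter fraction range.
#' @param missingness_rate Fraction of daily records dropped at random.
#' @param month_dropout_rate Fraction of whole months dropped.
#' @param vlm_p5,vlm_p95 Percentile pins (mm/yr) of the differential
#'   vertical-land-motion band from which true rates are drawn for sites
#'   whose instruments do not both reach the basement.
#' @param gsl_trend True trend (mm/yr) of the reference geocentric
#'   sea-level series.
#' @param rwl_intercept Water elevation (m) at the window start.
#' @param sec_intercept_range Range (m) of wetland surface elevation at the
#'   window start.
#' @param survey_year Geodetic survey year (elevation-correction pivot).
#' @param seed Master integer seed.
#'
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sites = 253,
                             start = "2009-01-01", end = "2021-12-31",
                             rwl_trend_range = c(5, 25),
                             sec_trend_range = c(0, 12),
                             seasonal_amplitude = 100,
                             ar1_phi_range = c(0.2, 0.6),
                             innovation_sd = 25,
                             daily_noise_sd = 5,
                             shared_signal_weight = 1,
                             shared_phi = 0.5,
                             shared_innovation_sd = 30,
                             sec_noise_sd = 15,
                             sec_missingness_rate = 0.05,
                             gauge_depth_range = c(4, 5),
                             rset_depth_default = 20,
                             hp_depth_range = c(0.5, 50),
                             tidal_amplitude_range = c(0.2, 0.6),
                             organic_fraction_range = c(0.05, 0.85),
                             missingness_rate = 0.08,
                             month_dropout_rate = 0.03,
                             vlm_p5 = 1, vlm_p95 = 4,
                             gsl_trend = 10.5,
                             rwl_intercept = 0,
                             sec_intercept_range = c(-0.20, 0.30),
                             survey_year = 2014,
                             seed = 1L) {
  start <- as.Date(start); end <- as.Date(end)
  if (length(month_seq(start, end)) < 24) {
    stop("study window shorter than 24 months: too short for deseasonalization")
  }
  chk_range <- function(r, name) {
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2]) {
      stop(sprintf("`%s` must be a non-decreasing length-2 range", name))
    }
  }
  chk_range(rwl_trend_range, "rwl_trend_range")
  chk_range(sec_trend_range, "sec_trend_range")
  chk_range(ar1_phi_range, "ar1_phi_range")
  chk_range(gauge_depth_range, "gauge_depth_range")
  chk_range(hp_depth_range, "hp_depth_range")
  chk_range(tidal_amplitude_range, "tidal_amplitude_range")
  chk_range(organic_fraction_range, "organic_fraction_range")
  chk_range(sec_intercept_range, "sec_intercept_range")
  if (any(abs(ar1_phi_range) >= 1) || abs(shared_phi) >= 1) {
    stop("AR(1) coefficients must lie strictly inside (-1, 1)")
  }
  if (missingness_rate < 0 || missingness_rate >= 1) {
    stop("missingness_rate must lie in [0, 1)")
  }
  if (shared_signal_weight < 0 || shared_signal_weight > 1) {
    stop("shared_signal_weight must lie in [0, 1]")
  }
  cfg <- as.list(environment())
  cfg$chk_range <- NULL
  structure(cfg, class = "synthetic_config")
}

# Deterministic (noise-free) daily water elevation for one site, in m.
# `t_dec` decimal years; t0 the window-start decimal year.
det_water <- function(t_dec, t0, intercept_m, rwl_trend_mm_yr,
                      seasonal_amplitude_mm, phase) {
  intercept_m + (rwl_trend_mm_yr / 1000) * (t_dec - t0) +
    (seasonal_amplitude_mm / 1000) * sin(2 * pi * (t_dec - phase))
}

# Deterministic wetland surface elevation, in m.
det_wetland <- function(t_dec, t0, intercept_m, sec_trend_mm_yr) {
  intercept_m + (sec_trend_mm_yr / 1000) * (t_dec - t0)
}

# Monthly AR(1) path of length n (mm), stationary start.
ar1_path <- function(n, phi, innovation_sd) {
  if (innovation_sd == 0) return(rep(0, n))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, innovation_sd / sqrt(1 - phi^2))
  if (n > 1) {
    e <- stats::rnorm(n - 1, 0, innovation_sd)
    for (t in 2:n) x[t] <- phi * x[t - 1] + e[t - 1]
  }
  x
}

# Shared monthly ocean signal (mm), regenerated identically from the master
# seed by both the network generator and the reference-series generator.
shared_signal <- function(config, n_months) {
  with_seed(derive_seed(config$seed, 0L, "shared_signal"),
            ar1_path(n_months, config$shared_phi, config$shared_innovation_sd))
}

# Biannual surface-elevation measurement dates within the window
# (mid-March and mid-September of each year).
sec_dates <- function(start, end) {
  yrs <- seq(as.integer(format(start, "%Y")), as.integer(format(end, "%Y")))
  d <- sort(as.Date(c(paste0(yrs, "-03-15"), paste0(yrs, "-09-15"))))
  d[d >= start & d <= end]
}

#' Generate a synthetic monitoring network with known ground truth
#'
#' Produces per-site station metadata, daily water-level series, biannual
#' wetland surface-elevation series, and a ground-truth table holding the
#' generating parameters plus the response category that the classification
#' rules assign to the noise-free system. Regeneration with the same
#' configuration (including seed) is bit-identical.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_network`: `stations` (data frame),
#'   `rwl` (named list of daily [level_series()]), `sec` (named list of
#'   biannual [level_series()]), `truth` (data frame), `config`.
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  start <- config$start; end <- config$end
  days <- seq(start, end, by = "day")
  ty <- decimal_year(days)
  t0 <- decimal_year(start)
  months <- month_seq(start, end)
  n_m <- length(months)
  month_idx <- match(month_floor(days), months)
  s_shared <- shared_signal(config, n_m)
  sdates <- sec_dates(start, end)
  ty_sec <- decimal_year(sdates)

  runif_r <- function(r) stats::runif(1, r[1], r[2])
  vlm_sd <- (config$vlm_p95 - config$vlm_p5) / (2 * stats::qnorm(0.95))
  vlm_mean <- (config$vlm_p5 + config$vlm_p95) / 2

  stations <- vector("list", config$n_sites)
  rwl <- vector("list", config$n_sites)
  sec <- vector("list", config$n_sites)
  truth <- vector("list", config$n_sites)

  for (i in seq_len(config$n_sites)) {
    site_id <- sprintf("SYN%04d", i)
    with_seed(derive_seed(config$seed, i, "site_params"), {
      crwl_trend <- runif_r(config$rwl_trend_range)
      sec_trend <- runif_r(config$sec_trend_range)
      phi <- runif_r(config$ar1_phi_range)
      phase <- stats::runif(1)
      gauge_depth <- runif_r(config$gauge_depth_range)
      hp_depth <- runif_r(config$hp_depth_range)
      tidal_amp <- runif_r(config$tidal_amplitude_range)
      organic <- runif_r(config$organic_fraction_range)
      sec_int <- runif_r(config$sec_intercept_range)
      lon <- stats::runif(1, -94, -88.8)
      lat <- stats::runif(1, 28.8, 30.6)
      vlm_draw <- stats::rnorm(1, vlm_mean, vlm_sd)
    })
    rset_depth <- config$rset_depth_default
    needs_vlm <- !(rset_depth >= hp_depth && gauge_depth >= hp_depth)
    vlm_rate <- if (needs_vlm) vlm_draw else 0
    rwl_trend <- crwl_trend + vlm_rate

    # water series: deterministic skeleton + shared signal + monthly AR(1)
    # + daily white noise, then missingness
    det_d <- det_water(ty, t0, config$rwl_intercept, rwl_trend,
                       config$seasonal_amplitude, phase)
    noise <- with_seed(derive_seed(config$seed, i, "site_noise"), {
      e_m <- ar1_path(n_m, phi, config$innovation_sd)
      e_d <- if (config$daily_noise_sd > 0) {
        stats::rnorm(length(days), 0, config$daily_noise_sd)
      } else rep(0, length(days))
      list(monthly = e_m, daily = e_d)
    })
    vals <- det_d +
      (config$shared_signal_weight * s_shared[month_idx] +
         noise$monthly[month_idx] + noise$daily) / 1000
    vals <- with_seed(derive_seed(config$seed, i, "missingness"), {
      if (config$missingness_rate > 0) {
        vals[stats::runif(length(vals)) < config$missingness_rate] <- NA_real_
      }
      if (config$month_dropout_rate > 0) {
        gone <- which(stats::runif(n_m) < config$month_dropout_rate)
        vals[month_idx %in% gone] <- NA_real_
      }
      vals
    })
    rwl[[i]] <- level_series(site_id, days, vals, "daily")

    # wetland surface series: linear + white noise, occasional dropouts
    sec_vals <- det_wetland(ty_sec, t0, sec_int, sec_trend)
    sec_vals <- with_seed(derive_seed(config$seed, i, "sec_noise"), {
      v <- sec_vals + stats::rnorm(length(sec_vals), 0, config$sec_noise_sd / 1000)
      if (config$sec_missingness_rate > 0) {
        v[stats::runif(length(v)) < config$sec_missingness_rate] <- NA_real_
      }
      v
    })
    sec[[i]] <- level_series(site_id, sdates, sec_vals, "biannual",
                             completeness = as.numeric(!is.na(sec_vals)))

    stations[[i]] <- data.frame(
      site_id = site_id, lon = lon, lat = lat,
      rset_depth_m = rset_depth, gauge_depth_m = gauge_depth,
      hp_depth_m = hp_depth, survey_year = config$survey_year,
      tidal_amplitude_m = tidal_amp, organic_fraction = organic)

    truth[[i]] <- cbind(
      data.frame(site_id = site_id,
                 rwl_trend_mm_yr = rwl_trend,
                 crwl_trend_mm_yr = crwl_trend,
                 sec_trend_mm_yr = sec_trend,
                 vlm_rate_mm_yr = vlm_rate,
                 phi = phi,
                 requires_vlm = needs_vlm),
      noise_free_truth(config, days, ty, t0, months, month_idx,
                       rwl_trend, vlm_rate, phase, tidal_amp,
                       sdates, ty_sec, sec_int, sec_trend,
                       crwl_trend))
  }
  names(rwl) <- names(sec) <- vapply(stations, function(s) s$site_id, "")
  empty_stations <- data.frame(
    site_id = character(), lon = numeric(), lat = numeric(),
    rset_depth_m = numeric(), gauge_depth_m = numeric(),
    hp_depth_m = numeric(), survey_year = numeric(),
    tidal_amplitude_m = numeric(), organic_fraction = numeric())
  structure(
    list(stations = if (config$n_sites > 0) do.call(rbind, stations) else empty_stations,
         rwl = rwl, sec = sec,
         truth = if (config$n_sites > 0) do.call(rbind, truth) else data.frame(site_id = character()),
         config = config),
    class = "synthetic_network"
  )
}

# Classification of the noise-free system: deterministic daily water is
# aggregated to monthly exactly as the pipeline does, corrected with the
# true differential VLM rate around the survey year, and compared with the
# deterministic wetland surface at measurement occasions.
noise_free_truth <- function(config, days, ty, t0, months, month_idx,
                             rwl_trend, vlm_rate, phase, tidal_amp,
                             sdates, ty_sec, sec_int, sec_trend, crwl_trend) {
  det_d <- det_water(ty, t0, config$rwl_intercept, rwl_trend,
                     config$seasonal_amplitude, phase)
  monthly_val <- vapply(seq_along(months),
                        function(m) mean(det_d[month_idx == m]), 0)
  monthly <- level_series("truth", months, monthly_val, "monthly")
  corrected <- correct_elevations(monthly, vlm_rate, config$survey_year)
  tides <- tide_triplet(corrected, tidal_amp)
  wetland <- level_series("truth", sdates,
                          det_wetland(ty_sec, t0, sec_int, sec_trend),
                          "biannual")
  p_rate <- as.numeric(crwl_trend > sec_trend)
  out <- data.frame(p_rate_true = p_rate)
  for (cond in c("low", "mean", "high")) {
    pf <- flooding_probability(wetland, tides, cond)
    out[[paste0("p_flood_", cond, "_true")]] <- pf
    out[[paste0("category_", cond, "_true")]] <- classify_site(p_rate, pf)
  }
  out
}

#' Generate the reference geocentric sea-level series
#'
#' A monthly series carrying the same common ocean signal that is injected
#' into every site's water-level series, on top of a linear trend. Plays the
#' role of a regional open-water reference (pooled altimetry points or a
#' motion-corrected tide gauge) for site-vs-reference correlation analysis.
#'
#' @param config A [synthetic_config()].
#' @return A monthly [level_series()] with site id `"GSLREF"`.
#' @export
generate_reference_gsl <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  months <- month_seq(config$start, config$end)
  ty <- decimal_year(months)
  t0 <- decimal_year(config$start)
  s <- shared_signal(config, length(months))
  vals <- (config$gsl_trend / 1000) * (ty - t0) + s / 1000
  level_series("GSLREF", months, vals, "monthly")
}

#' Default synthetic sea-level-rise projection scenarios
#'
#' Three synthetic stand-in scenario curves on a 2030-2150 decadal grid,
#' shaped like low/medium/high emissions pathways: a low pathway that
#' plateaus, a middle pathway that climbs through 7 mm/yr around 2070, and a
#' high pathway that keeps accelerating. These are illustrative defaults for
#' testing, not a published projection product.
#'
#' @return Named list of `list(years, rate_mm_yr, sigma_mm_yr)` per scenario.
#' @export
default_projection_scenarios <- function() {
  years <- seq(2030, 2150, by = 10)
  n <- length(years)
  list(
    "low" = list(years = years,
                 rate_mm_yr = 4.2 + 1.6 * (seq_len(n) - 1) / (n - 1),
                 sigma_mm_yr = rep(1.2, n)),
    "medium" = list(years = years,
                    rate_mm_yr = seq(4.6, 11.8, length.out = n),
                    sigma_mm_yr = seq(1.2, 2.4, length.out = n)),
    "high" = list(years = years,
                  rate_mm_yr = 4.8 + 9.6 * ((seq_len(n) - 1) / (n - 1))^1.3,
                  sigma_mm_yr = seq(1.4, 3.2, length.out = n))
  )
}

#' Generate per-location projection curves around target scenario curves
#'
#' Emulates a set of coastal projection locations whose decadal rate curves
#' scatter around a regional scenario curve; the per-location offsets are
#' centered so the unweighted spatial mean reproduces the target curve
#' exactly.
#'
#' @param scenario_params Named list per scenario of `list(years,
#'   rate_mm_yr, sigma_mm_yr)`; default [default_projection_scenarios()].
#' @param n_locations Number of locations; default 16.
#' @param location_spread Standard deviation (mm/yr) of per-location offsets
#'   before centering.
#' @param seed Integer seed.
#' @return Data frame with columns `scenario`, `location_id`, `year`,
#'   `rate_mm_yr`, `sigma_mm_yr`.
#' @export
generate_projection_curves <- function(scenario_params = default_projection_scenarios(),
                                       n_locations = 16,
                                       location_spread = 0.3,
                                       seed = 1L) {
  rows <- list()
  for (sc in names(scenario_params)) {
    p <- scenario_params[[sc]]
    if (any(p$sigma_mm_yr < 0)) stop("sigma band values must be non-negative")
    if (length(p$rate_mm_yr) != length(p$years) ||
        length(p$sigma_mm_yr) != length(p$years)) {
      stop("scenario '", sc, "': years, rates and sigmas differ in length")
    }
    delta <- with_seed(derive_seed(seed, match(sc, names(scenario_params)), "proj"),
                       stats::rnorm(n_locations, 0, location_spread))
    delta <- delta - mean(delta)
    for (loc in seq_len(n_locations)) {
      rows[[length(rows) + 1]] <- data.frame(
        scenario = sc,
        location_id = sprintf("LOC%02d", loc),
        year = p$years,
        rate_mm_yr = p$rate_mm_yr + delta[loc],
        sigma_mm_yr = p$sigma_mm_yr)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
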