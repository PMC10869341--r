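#' Ordinary-least-squares trend of a level series
#'
#' Regresses elevation (m) on decimal year, centered on the midpoint of the
#' observed stamps, and reports the slope in mm/yr. Residuals (in mm) and
#' the centered time grid are retained for AR(1) fitting and surrogate
#' construction.
#'
#' @param series A [level_series()] with at least 3 observed values.
#' @return An object of class `trend_fit` with elements `rate_mm_yr`,
#'   `intercept_m` (value at the centered origin), `residual_sd_mm`,
#'   `residuals_mm`, `time_dec` (centered decimal years of all stamps),
#'   `observed` (logical mask), `n`.
#' @export
ols_trend <- function(series) {
  stopifnot(inherits(series, "level_series"))
  obs <- !is.na(series$value)
  n <- sum(obs)
  if (n < 3) stop("need at least 3 observed values for a trend")
  t_dec <- decimal_year(series$time)
  if (diff(range(t_dec[obs])) == 0) stop("all timestamps equal: rank-deficient design")
  tc <- t_dec - mean(t_dec[obs])
  fit <- stats::lm.fit(cbind(1, tc[obs]), series$value[obs])
  res_mm <- fit$residuals * 1000
  structure(
    list(site_id = series$site_id,
         rate_mm_yr = unname(fit$coefficients[2]) * 1000,
         intercept_m = unname(fit$coefficients[1]),
         residual_sd_mm = stats::sd(res_mm),
         residuals_mm = res_mm,
         time_dec = tc,
         observed = obs,
         n = n),
    class = "trend_fit"
  )
}

#' Fit a first-order autoregressive model to regression residuals
#'
#' The lag-1 coefficient is the lag-1 sample autocorrelation of the
#' residuals; the innovation standard deviation follows from the stationary
#' variance relation `sd_innov = sd_resid * sqrt(1 - phi^2)`.
#'
#' With `correct_bias = TRUE`, a small-sample correction is applied before
#' the variance relation: the sample autocorrelation of residuals from an
#' intercept-plus-trend regression is downward-biased by about
#' `(2 + 4 phi) / n` (the Marriott-Pope bias, doubled because two regression
#' parameters were removed), and the residual variance underestimates the
#' marginal noise variance by a factor `1 - 2 (1 + phi) / ((1 - phi) n)`.
#' Without the correction, surrogate-based significance tests built from the
#' fitted model reject somewhat more often than their nominal level on
#' persistent noise; the corrected fit is used for inference.
#'
#' @param residuals_mm Numeric residuals in mm on a near-regular grid,
#'   length >= 12.
#' @param correct_bias Apply the small-sample bias correction (default
#'   `FALSE`: report the raw sample autocorrelation).
#' @param extra_dof Additional mean-like degrees of freedom absorbed
#'   upstream of the trend fit, used in the variance inflation when
#'   `correct_bias = TRUE`. Climatology removal costs 11 (twelve monthly
#'   offsets, one lost to mean-centering); these act on the residual
#'   variance like white-noise dof because calendar months are a full
#'   AR(1) decorrelation length apart.
#' @return List of class `ar1_model` with `phi` and `innovation_sd_mm`.
#' @export
fit_ar1 <- function(residuals_mm, correct_bias = FALSE, extra_dof = 0) {
  x <- residuals_mm[!is.na(residuals_mm)]
  n <- length(x)
  if (n < 12) stop("need at least 12 residuals to fit AR(1)")
  x <- x - mean(x)
  denom <- sum(x^2)
  phi <- if (denom > 0) sum(x[-1] * x[-n]) / denom else 0
  if (abs(phi) >= 1) {
    stop("estimated |phi| >= 1; the AR(1) model is inappropriate here - use white-noise surrogates")
  }
  s2 <- stats::var(x)
  if (correct_bias) {
    phi <- min(phi + (2 + 4 * phi) / n, 0.99)
    s2 <- s2 / max(1 - 2 * (1 + phi) / ((1 - phi) * n) - extra_dof / n, 0.5)
  }
  structure(list(phi = phi, innovation_sd_mm = sqrt(s2 * (1 - phi^2))),
            class = "ar1_model")
}

#' Simulate stationary AR(1) red-noise surrogate paths
#'
#' Each path starts from the stationary distribution (no burn-in) and
#' follows `x[t] = phi * x[t-1] + e[t]` with independent Gaussian
#' innovations.
#'
#' @param model An `ar1_model` from [fit_ar1()] (or constructed directly).
#' @param n_points Path length (>= 2).
#' @param n_draws Number of surrogate paths; default 10000.
#' @param seed Integer seed; the caller's RNG state is untouched.
#' @return Numeric matrix `n_points x n_draws`, in mm.
#' @export
simulate_surrogates <- function(model, n_points, n_draws = 10000, seed = NULL) {
  stopifnot(inherits(model, "ar1_model"))
  if (n_points < 2) stop("surrogate paths need at least 2 points")
  phi <- model$phi
  s <- model$innovation_sd_mm
  with_seed(seed, {
    out <- matrix(0, n_points, n_draws)
    sd_stat <- if (abs(phi) < 1) s / sqrt(1 - phi^2) else s
    out[1, ] <- stats::rnorm(n_draws, 0, sd_stat)
    if (n_points > 1 && s >= 0) {
      innov <- matrix(stats::rnorm((n_points - 1) * n_draws, 0, s),
                      n_points - 1, n_draws)
      for (t in 2:n_points) {
        out[t, ] <- phi * out[t - 1, ] + innov[t - 1, ]
      }
    }
    out
  })
}

#' Simulate white-noise surrogate paths
#'
#' The temporally uncorrelated special case used for short biannual
#' surface-elevation records, where an AR(1) fit is not supported by the
#' record length.
#'
#' @param residual_sd_mm Marginal standard deviation in mm.
#' @param n_points Path length.
#' @param n_draws Number of paths; default 10000.
#' @param seed Integer seed.
#' @return Numeric matrix `n_points x n_draws`, in mm.
#' @export
white_noise_surrogates <- function(residual_sd_mm, n_points, n_draws = 10000,
                                   seed = NULL) {
  model <- structure(list(phi = 0, innovation_sd_mm = residual_sd_mm),
                     class = "ar1_model")
  simulate_surrogates(model, n_points, n_draws, seed)
}

# OLS slopes (mm/yr) of many surrogate paths sharing one time grid and
# missingness mask. `surrogates` is n_points x n_draws in mm; `time_dec`
# centered decimal years; `observed` logical mask applied to both. When
# `month` (calendar-month index 1..12 per stamp) is supplied, each path is
# passed through the same climatology-removal estimator the observed series
# went through (detrend, average per calendar month, mean-center, subtract)
# before its slope is taken, so the bootstrap replicates the full
# estimation chain.
surrogate_slopes <- function(surrogates, time_dec, observed, month = NULL) {
  tc <- time_dec[observed]
  tc <- tc - mean(tc)
  s <- surrogates[observed, , drop = FALSE]
  if (!is.null(month)) {
    mon <- month[observed]
    x <- cbind(1, tc)
    resid <- s - x %*% solve(crossprod(x), crossprod(x, s))
    clim <- rowsum(resid, mon) / as.vector(table(mon))
    clim <- sweep(clim, 2, colMeans(clim))
    s <- s - clim[match(mon, sort(unique(mon))), , drop = FALSE]
  }
  drop(crossprod(tc, s)) / sum(tc^2)
}

#' Surrogate-based significance of an observed trend
#'
#' Compares the magnitude of the observed OLS slope with the slopes of
#' trendless surrogate paths sampled on the same time grid with the same
#' missingness. The two-sided p-value uses the add-one estimator
#' `(k + 1) / (n + 1)` so it can never be exactly zero.
#'
#' @param fit A `trend_fit` from [ols_trend()].
#' @param surrogates Matrix from [simulate_surrogates()] with `n_points`
#'   equal to the full stamp count of the fitted series.
#' @param month Optional calendar-month index (1-12) per stamp; when the
#'   observed series was deseasonalized, supplying this passes each
#'   surrogate through the same climatology-removal estimator so the null
#'   distribution replicates the full chain.
#' @return p-value in (0, 1\].
#' @export
trend_p_value <- function(fit, surrogates, month = NULL) {
  stopifnot(inherits(fit, "trend_fit"))
  if (nrow(surrogates) != length(fit$time_dec)) {
    stop("surrogate length does not match the series grid")
  }
  slopes <- surrogate_slopes(surrogates, fit$time_dec, fit$observed, month)
  k <- sum(abs(slopes) >= abs(fit$rate_mm_yr))
  (k + 1) / (length(slopes) + 1)
}

#' Correlation between two detrended series with surrogate significance
#'
#' Computes the Pearson correlation over the common observed months and a
#' p-value from independent surrogate pairs: both series are replaced by
#' AR(1) surrogates with their own fitted models, and the p-value is the
#' add-one fraction of surrogate pairs whose |r| reaches the observed |r|.
#'
#' @param series_a,series_b Detrended monthly [level_series()] on a common
#'   calendar (matched by stamp).
#' @param model_a,model_b `ar1_model`s for the two series.
#' @param n_draws Number of surrogate pairs; default 10000.
#' @param seed Integer seed.
#' @return List with `r`, `p_value`, `n_common`.
#' @export
correlation_p_value <- function(series_a, series_b, model_a, model_b,
                                n_draws = 10000, seed = NULL) {
  common <- as.Date(intersect(series_a$time, series_b$time),
                    origin = "1970-01-01")
  ia <- match(common, series_a$time)
  ib <- match(common, series_b$time)
  ok <- !is.na(series_a$value[ia]) & !is.na(series_b$value[ib])
  n <- sum(ok)
  if (n < 24) stop("fewer than 24 common observed months")
  xa <- series_a$value[ia][ok]
  xb <- series_b$value[ib][ok]
  r <- stats::cor(xa, xb)
  sa <- simulate_surrogates(model_a, n, n_draws, seed = derive_seed(seed %||% 0, 1L, "corr_a"))
  sb <- simulate_surrogates(model_b, n, n_draws, seed = derive_seed(seed %||% 0, 2L, "corr_b"))
  sa <- sweep(sa, 2, colMeans(sa))
  sb <- sweep(sb, 2, colMeans(sb))
  r_surr <- colSums(sa * sb) /
    sqrt(colSums(sa^2) * colSums(sb^2))
  k <- sum(abs(r_surr) >= abs(r))
  list(r = r, p_value = (k + 1) / (n_draws + 1), n_common = n)
}

#' Monte Carlo trend ensemble by parametric residual bootstrap
#'
#' Each ensemble member is the fitted line plus one surrogate residual path
#' (AR(1) red noise for monthly water-level series, white noise for
#' biannual surface-elevation series), masked to the observed stamps and
#' refit by OLS. The resulting slopes form the sampling distribution of the
#' trend used by all downstream probability statements.
#'
#' @param fit A `trend_fit` from [ols_trend()].
#' @param model An `ar1_model` (use `phi = 0` for white noise), or `NULL` to
#'   use white noise at the fitted residual sd.
#' @param n_draws Ensemble size; default 10000.
#' @param seed Integer seed.
#' @param surrogates Optional pre-computed surrogate matrix (full grid).
#' @param month Optional calendar-month index (1-12) per stamp; supply it
#'   when the fitted series was deseasonalized, so every bootstrap
#'   replication re-estimates and removes the climatology exactly as the
#'   observed series did (see [trend_p_value()]).
#' @return An object of class `trend_ensemble`: `rate_mm_yr`, `draws_mm_yr`
#'   (length `n_draws`), `residual_sd_mm`, `seed`, `site_id`.
#' @export
trend_ensemble <- function(fit, model = NULL, n_draws = 10000, seed = NULL,
                           surrogates = NULL, month = NULL) {
  stopifnot(inherits(fit, "trend_fit"))
  if (is.null(model)) {
    model <- structure(list(phi = 0, innovation_sd_mm = fit$residual_sd_mm),
                       class = "ar1_model")
  }
  if (is.null(surrogates)) {
    surrogates <- simulate_surrogates(model, length(fit$time_dec), n_draws, seed)
  }
  slopes <- surrogate_slopes(surrogates, fit$time_dec, fit$observed, month)
  structure(
    list(site_id = fit$site_id,
         rate_mm_yr = fit$rate_mm_yr,
         draws_mm_yr = fit$rate_mm_yr + slopes,
         residual_sd_mm = fit$residual_sd_mm,
         p_value = NA_real_,
         seed = seed),
    class = "trend_ensemble"
  )
}

#' @export
print.trend_ensemble <- function(x, ...) {
  cat(sprintf("<trend_ensemble> site %s: %.2f mm/yr (ensemble sd %.2f, %d draws)\n",
              x$site_id, x$rate_mm_yr, stats::sd(x$draws_mm_yr),
              length(x$draws_mm_yr)))
  invisible(x)
}

#' Unweighted mean of per-point trend rates
#'
#' Used to pool the rates of many nearby measurement points (for example
#' altimetry points within coastal bands) into one regional rate.
#'
#' @param rates_mm_yr Numeric vector of per-point OLS rates.
#' @return Mean rate in mm/yr.
#' @export
pooled_point_rate <- function(rates_mm_yr) {
  if (length(rates_mm_yr) == 0) stop("no rates to pool")
  mean(rates_mm_yr)
}
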