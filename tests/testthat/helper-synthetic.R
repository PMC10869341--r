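# Small-network configuration factories used across the test files.

# A compact noisy network: 5 years, modest noise, deterministic seed.
small_config <- function(n_sites = 10, seed = 101, ...) {
  synthetic_config(n_sites = n_sites, start = "2009-01-01", end = "2013-12-31",
                   seed = seed, ...)
}

# Noise-free limit: every stochastic amplitude at zero, no gaps. The
# generated series are exact deterministic curves and ground truth is
# recovered exactly.
noise_free_config <- function(n_sites = 10, seed = 202, seasonal_amplitude = 0,
                              ...) {
  synthetic_config(n_sites = n_sites, start = "2009-01-01", end = "2021-12-31",
                   seasonal_amplitude = seasonal_amplitude,
                   innovation_sd = 0, daily_noise_sd = 0,
                   shared_signal_weight = 0, shared_innovation_sd = 0,
                   sec_noise_sd = 0, sec_missingness_rate = 0,
                   missingness_rate = 0, month_dropout_rate = 0,
                   seed = seed, ...)
}

# Monthly level series on a regular calendar grid starting 2009-01.
monthly_series <- function(values, start = "2009-01-01", site = "T1",
                           completeness = NULL) {
  months <- seq(as.Date(start), by = "month", length.out = length(values))
  level_series(site, months, values, "monthly", completeness = completeness)
}

# Brute-force OLS slope via the normal equations, independent of the
# package's fitting path.
brute_force_slope <- function(t, y) {
  ok <- !is.na(y)
  t <- t[ok]; y <- y[ok]
  t <- t - mean(t)   # center for numerical conditioning; slope is invariant
  n <- length(t)
  (n * sum(t * y) - sum(t) * sum(y)) / (n * sum(t^2) - sum(t)^2)
}
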