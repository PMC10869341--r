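test_that("config validation rejects degenerate inputs", {
  expect_error(synthetic_config(start = "2009-01-01", end = "2010-06-30"),
               "24 months")
  expect_error(synthetic_config(ar1_phi_range = c(0.5, 1.0)), "strictly inside")
  expect_error(synthetic_config(missingness_rate = 1), "missingness_rate")
  expect_error(synthetic_config(shared_signal_weight = 1.5), "0, 1")
  expect_error(synthetic_config(rwl_trend_range = c(10, 5)), "range")
})

test_that("noise-free series are exact lines with the recorded true trends", {
  net <- generate_network(noise_free_config(n_sites = 4))
  for (i in 1:4) {
    monthly <- aggregate_series(net$rwl[[i]], "monthly")
    expect_equal(ols_trend(monthly)$rate_mm_yr, net$truth$rwl_trend_mm_yr[i],
                 tolerance = 1e-4)
    expect_equal(ols_trend(net$sec[[i]])$rate_mm_yr, net$truth$sec_trend_mm_yr[i],
                 tolerance = 1e-9)
    expect_equal(ols_trend(net$sec[[i]])$residual_sd_mm, 0, tolerance = 1e-9)
  }
})

test_that("regeneration with the same seed is bit-identical", {
  cfg <- small_config(n_sites = 3, seed = 77)
  n1 <- generate_network(cfg)
  n2 <- generate_network(cfg)
  expect_identical(n1$stations, n2$stations)
  expect_identical(n1$rwl, n2$rwl)
  expect_identical(n1$sec, n2$sec)
  expect_identical(n1$truth, n2$truth)
  expect_identical(generate_reference_gsl(cfg), generate_reference_gsl(cfg))
  n3 <- generate_network(small_config(n_sites = 3, seed = 78))
  expect_false(identical(n1$rwl, n3$rwl))
})

test_that("generated residuals carry the configured AR(1) structure", {
  cfg <- synthetic_config(n_sites = 200, start = "2009-01-01",
                          end = "2021-12-31",
                          ar1_phi_range = c(0.5, 0.5), innovation_sd = 20,
                          daily_noise_sd = 0, seasonal_amplitude = 0,
                          shared_signal_weight = 0, missingness_rate = 0,
                          month_dropout_rate = 0, seed = 303)
  net <- generate_network(cfg)
  ac1 <- vapply(net$rwl, function(s) {
    r <- detrend(aggregate_series(s, "monthly"))$value
    r <- r - mean(r)
    sum(r[-1] * r[-length(r)]) / sum(r^2)
  }, 0)
  expect_lt(abs(mean(ac1) - 0.5), 0.05)
  # stationary variance: var = innovation^2 / (1 - phi^2)
  v <- vapply(net$rwl, function(s) {
    stats::var(detrend(aggregate_series(s, "monthly"))$value) * 1e6
  }, 0)
  expect_equal(mean(v), 20^2 / (1 - 0.25), tolerance = 0.1)
})

test_that("the shared ocean signal couples sites to the reference", {
  # zero loading: detrended site-reference correlation centers on zero
  cfg0 <- synthetic_config(n_sites = 60, start = "2009-01-01", end = "2021-12-31",
                           shared_signal_weight = 0, seasonal_amplitude = 0,
                           missingness_rate = 0, month_dropout_rate = 0,
                           daily_noise_sd = 0, seed = 404)
  net0 <- generate_network(cfg0)
  ref0 <- detrend(generate_reference_gsl(cfg0))
  r0 <- vapply(net0$rwl, function(s) {
    cor(detrend(aggregate_series(s, "monthly"))$value, ref0$value)
  }, 0)
  expect_lt(abs(mean(r0)), 0.05)

  # unit loading and no site noise: detrended series equal the detrended
  # reference month by month
  cfg1 <- synthetic_config(n_sites = 2, start = "2009-01-01", end = "2021-12-31",
                           shared_signal_weight = 1, seasonal_amplitude = 0,
                           innovation_sd = 0, daily_noise_sd = 0,
                           missingness_rate = 0, month_dropout_rate = 0,
                           seed = 405)
  net1 <- generate_network(cfg1)
  ref1 <- detrend(generate_reference_gsl(cfg1))
  site1 <- detrend(aggregate_series(net1$rwl[[1]], "monthly"))
  expect_equal(site1$value, ref1$value, tolerance = 1e-3)
})

test_that("the reference series recovers its configured trend", {
  cfg <- synthetic_config(n_sites = 1, gsl_trend = 10.7,
                          shared_innovation_sd = 0, seed = 1)
  ref <- generate_reference_gsl(cfg)
  expect_equal(ols_trend(ref)$rate_mm_yr, 10.7, tolerance = 1e-6)
})

test_that("ground-truth categories match the pipeline on noise-free sites", {
  cfg <- noise_free_config(n_sites = 12, seed = 505, seasonal_amplitude = 80)
  net <- generate_network(cfg)
  known <- setNames(net$truth$vlm_rate_mm_yr, net$truth$site_id)
  run <- run_pipeline(net, n_draws = 200, seed = 1, vlm_mode = "known",
                      known_vlm_rates = known)
  for (cond in c("low", "mean", "high")) {
    expect_identical(run$classification[[paste0("category_", cond)]],
                     net$truth[[paste0("category_", cond, "_true")]])
  }
  expect_equal(run$classification$p_flood_low, net$truth$p_flood_low_true,
               tolerance = 1e-12)
})

test_that("projection curve generation averages back to the target curve", {
  curves <- generate_projection_curves(seed = 7)
  avg <- average_locations(curves)
  base <- default_projection_scenarios()
  for (sc in names(base)) {
    got <- avg[avg$scenario == sc, ]
    expect_equal(got$rate_mm_yr, base[[sc]]$rate_mm_yr, tolerance = 1e-9)
    expect_equal(got$sigma_mm_yr, base[[sc]]$sigma_mm_yr, tolerance = 1e-12)
  }
  # constant curve stays constant; linear ramp interpolates its own rule
  const <- generate_projection_curves(
    list(flat = list(years = seq(2030, 2150, 10),
                     rate_mm_yr = rep(5, 13), sigma_mm_yr = rep(1, 13))),
    seed = 2)
  expect_equal(average_locations(const)$rate_mm_yr, rep(5, 13), tolerance = 1e-9)
  ramp <- list(lin = list(years = seq(2025, 2125, 10),
                          rate_mm_yr = seq(3, 13, length.out = 11),
                          sigma_mm_yr = rep(1, 11)))
  g <- generate_projection_curves(ramp, seed = 3)
  a <- average_locations(g)
  expect_equal(a$rate_mm_yr[a$year == 2075], 8, tolerance = 1e-9)
  expect_error(generate_projection_curves(
    list(bad = list(years = 2030, rate_mm_yr = 5, sigma_mm_yr = -1))),
    "non-negative")
})

test_that("fixtures round-trip losslessly and respect cardinality", {
  dir <- withr::local_tempdir()
  net <- generate_network(small_config(n_sites = 5, seed = 606))
  write_fixtures(net, dir)
  expect_error(write_fixtures(net, dir), "overwrite")
  back <- read_fixtures(dir)
  expect_equal(back$stations, net$stations, tolerance = 1e-12)
  expect_equal(length(back$rwl), 5)
  expect_equal(length(list.files(file.path(dir, "series"))), 10)
  for (id in names(net$rwl)) {
    expect_equal(back$rwl[[id]]$value, net$rwl[[id]]$value, tolerance = 1e-12)
    expect_identical(back$rwl[[id]]$time, net$rwl[[id]]$time)
    expect_equal(back$sec[[id]]$value, net$sec[[id]]$value, tolerance = 1e-12)
  }
  expect_equal(back$truth$rwl_trend_mm_yr, net$truth$rwl_trend_mm_yr,
               tolerance = 1e-12)

  # empty network: schema-valid but empty files
  dir2 <- withr::local_tempdir()
  empty <- generate_network(small_config(n_sites = 0, seed = 1))
  write_fixtures(empty, dir2)
  back2 <- read_fixtures(dir2)
  expect_equal(nrow(back2$stations), 0)
  expect_equal(length(back2$rwl), 0)

  # projections round-trip
  p <- generate_projection_curves(seed = 1)
  path <- file.path(dir, "proj.csv")
  write_projections(p, path)
  p2 <- read_projections(path)
  expect_equal(sort(names(p2)), sort(names(p)))
  expect_equal(average_locations(p2), average_locations(p), tolerance = 1e-12)
})
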