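mk_ens <- function(draws) {
  structure(list(site_id = "Z", rate_mm_yr = mean(draws), draws_mm_yr = draws,
                 residual_sd_mm = NA, seed = NULL), class = "trend_ensemble")
}

test_that("tide triplets bracket the mean tide by half the amplitude", {
  months <- seq(as.Date("2010-01-01"), by = "month", length.out = 3)
  s <- level_series("T", months, c(0.300, 0.250, 0.400), "monthly")
  tt <- tide_triplet(s, 0.40)
  expect_equal(tt$low_m[1], 0.100)
  expect_equal(tt$high_m[1], 0.500)
  expect_equal(tt$high_m - tt$low_m, rep(0.40, 3))

  tideless <- tide_triplet(s, 0)
  expect_equal(tideless$low_m, tideless$high_m)
  expect_error(tide_triplet(s, -0.1), "non-negative")
})

test_that("rate-exceedance probability matches closed forms and bounds", {
  set.seed(81)
  a <- mk_ens(rnorm(10000, 10, 1))
  b <- mk_ens(rnorm(10000, 5, 1))
  expect_equal(p_rate_exceed(a, b), pnorm(5 / sqrt(2)), tolerance = 0.005)

  lo <- mk_ens(rep(1, 100)); hi <- mk_ens(rep(2, 100))
  expect_equal(p_rate_exceed(lo, hi), 0)
  expect_equal(p_rate_exceed(hi, lo), 1)
  # identical degenerate ensembles: every pair ties, strict ">" gives 0
  expect_equal(p_rate_exceed(lo, lo), 0)
  # independent identically distributed ensembles: about one half
  c1 <- mk_ens(rnorm(10000, 5, 1)); c2 <- mk_ens(rnorm(10000, 5, 1))
  expect_equal(p_rate_exceed(c1, c2), 0.5, tolerance = 0.02)
  expect_error(p_rate_exceed(lo, mk_ens(rep(1, 7))), "draw count")
})

test_that("flooding probability counts measurement occasions and is tide-monotone", {
  months <- seq(as.Date("2010-01-01"), by = "month", length.out = 120)
  tides <- tide_triplet(level_series("T", months, rep(0.30, 120), "monthly"), 0.20)
  occasions <- months[seq(3, 120, by = 6)]
  # wetland always 0.2 m above high tide
  dry <- level_series("W", occasions, rep(0.60, 20), "biannual")
  expect_equal(flooding_probability(dry, tides, "low"), 0)
  expect_equal(flooding_probability(dry, tides, "mean"), 0)
  expect_equal(flooding_probability(dry, tides, "high"), 0)
  # below low tide on 19 of 20 occasions
  wet <- level_series("W2", occasions, c(rep(0.10, 19), 0.90), "biannual")
  expect_equal(flooding_probability(wet, tides, "low"), 0.95)
  # monotone in tide condition for an arbitrary site
  set.seed(9)
  rand <- level_series("W3", occasions, runif(20, 0.1, 0.5), "biannual")
  p <- vapply(c("low", "mean", "high"),
              function(cc) flooding_probability(rand, tides, cc), 0)
  expect_true(p[1] <= p[2] && p[2] <= p[3])
})

test_that("the seven category rules partition the probability square", {
  # quoted example rules
  expect_equal(classify_site(0.70, 0.95), "give-up (drowning complete)")
  expect_equal(classify_site(0.50, 0.05), "keep-up (stable equilibrium)")
  expect_equal(classify_site(0.20, 0.60), "catch-up")
  expect_equal(classify_site(0.20, 0.40), "speed-up")
  expect_equal(classify_site(0.70, 0.05), "give-up (drowning projected)")
  expect_equal(classify_site(0.70, 0.50), "give-up (drowning in progress)")
  expect_equal(classify_site(0.50, 0.50), "keep-up (dynamic equilibrium)")

  g <- expand.grid(p_rate = seq(0, 1, by = 0.01), p_flood = seq(0, 1, by = 0.01))
  cats <- classify_site(g$p_rate, g$p_flood)
  expect_true(all(cats %in% response_categories))
  expect_true(all(nchar(cats) > 0))
  expect_equal(length(unique(cats)), 7)
  expect_error(classify_site(1.2, 0.5), "0, 1")
})

test_that("category regions are connected rectangles on the grid", {
  step <- seq(0, 1, by = 0.01)
  g <- expand.grid(p_rate = step, p_flood = step)
  cats <- classify_site(g$p_rate, g$p_flood)
  for (cat in response_categories) {
    sel <- cats == cat
    rates <- g$p_rate[sel]; floods <- g$p_flood[sel]
    # rectangle: every grid point inside the bounding box carries the label
    inside <- g$p_rate >= min(rates) & g$p_rate <= max(rates) &
      g$p_flood >= min(floods) & g$p_flood <= max(floods)
    expect_true(all(cats[inside] == cat))
  }
})

test_that("deficit draws subtract pairwise and negate under swap", {
  a <- mk_ens(rep(15, 50)); b <- mk_ens(rep(6, 50))
  expect_equal(deficit_draws(a, b), rep(9, 50))
  set.seed(91)
  x <- mk_ens(rnorm(1000, 10, 2)); y <- mk_ens(rnorm(1000, 6, 2))
  expect_equal(deficit_draws(x, y), -deficit_draws(y, x))
  # medians are consistent for symmetric independent ensembles
  expect_equal(median(deficit_draws(x, y)) + median(y$draws_mm_yr),
               median(x$draws_mm_yr), tolerance = 0.3)
})

test_that("cross-site percentiles match a sort-and-interpolate oracle", {
  expect_equal(unname(cross_site_percentiles(1:5, 0.5)), 3)
  expect_equal(unname(cross_site_percentiles(rep(4.2, 10), c(0.1, 0.5, 0.9))),
               rep(4.2, 3))
  set.seed(101)
  x <- rnorm(101)
  probs <- c(0.25, 0.5, 0.9)
  got <- cross_site_percentiles(x, probs)
  xs <- sort(x)
  oracle <- vapply(probs, function(p) {
    h <- (length(xs) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    xs[lo] + (h - lo) * (xs[hi] - xs[lo])
  }, 0)
  expect_equal(unname(got), oracle, tolerance = 1e-12)
  expect_error(cross_site_percentiles(1:3), "at least 4")
})

test_that("rate correlation trims tails and detects collinearity and independence", {
  set.seed(111)
  crwl <- rnorm(200, 13, 4)
  # trimming count agrees with a sort oracle
  res <- rate_correlation(crwl, crwl * 0.5 + 1, n_perm = 200, seed = 3)
  qs <- quantile(crwl, c(0.025, 0.975))
  expect_equal(res$n_trimmed, sum(crwl < qs[1] | crwl > qs[2]))
  expect_equal(res$all$r, 1, tolerance = 1e-12)
  expect_equal(res$all$p_value, 1 / 201)

  # independent rates: small correlation, non-significant
  sec <- rnorm(200, 6, 3)
  org <- runif(200)
  res2 <- rate_correlation(crwl, sec, organic_fraction = org,
                           n_perm = 500, seed = 4)
  expect_lt(abs(res2$all$r), 0.2)
  expect_gt(res2$all$p_value, 0.05)
  expect_lt(abs(res2$organic$r), 0.3)
  expect_error(rate_correlation(rnorm(8), rnorm(8)), "length|10")
})

test_that("safe-site summary partitions categories", {
  cats <- rep(response_categories[1:3], c(3, 2, 1))
  s <- safe_site_summary(cats, rnorm(6, 12), rnorm(6, 5))
  expect_equal(s$safe_share, 0)
  expect_equal(sum(s$shares), 1)

  mixed <- response_categories[c(1, 1, 4, 6, 7, 2, 5)]
  s2 <- safe_site_summary(mixed, 1:7, 7:1)
  expect_equal(s2$safe_share, 4 / 7)
  expect_equal(sum(s2$shares), 1)
  expect_equal(s2$median_crwl_safe, median(c(3, 4, 5, 7)))
})
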