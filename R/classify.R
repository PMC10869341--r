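#' The seven wetland response categories
#'
#' Ordered factor levels used throughout: three give-up flavors (the wetland
#' cannot keep pace with corrected water-level rise), two keep-up flavors,
#' catch-up (gaining elevation despite frequent flooding) and speed-up
#' (gaining elevation under subaerial conditions).
#'
#' @export
response_categories <- c(
  "give-up (drowning complete)",
  "give-up (drowning in progress)",
  "give-up (drowning projected)",
  "keep-up (dynamic equilibrium)",
  "keep-up (stable equilibrium)",
  "catch-up",
  "speed-up"
)

#' Monthly low/mean/high tide levels from corrected water elevations
#'
#' The monthly corrected water elevation is taken as the mean tide; low and
#' high tide are obtained by subtracting and adding half the annual tidal
#' amplitude.
#'
#' @param mean_tide A monthly [level_series()] of corrected water elevations
#'   (m).
#' @param tidal_amplitude_m Annual tidal amplitude in meters, `>= 0`.
#' @return A data frame with columns `time`, `low_m`, `mean_m`, `high_m`.
#' @export
tide_triplet <- function(mean_tide, tidal_amplitude_m) {
  stopifnot(inherits(mean_tide, "level_series"))
  if (!is.finite(tidal_amplitude_m) || tidal_amplitude_m < 0) {
    stop("tidal amplitude must be non-negative")
  }
  data.frame(time = mean_tide$time,
             low_m = mean_tide$value - tidal_amplitude_m / 2,
             mean_m = mean_tide$value,
             high_m = mean_tide$value + tidal_amplitude_m / 2)
}

#' Probability that the corrected water-level rate exceeds the SEC rate
#'
#' The fraction of index-paired Monte Carlo draws where the corrected
#' relative water-level trend strictly exceeds the surface-elevation-change
#' trend. With degenerate identical ensembles every pair ties and the
#' returned value is 0 (the tie fraction is not split).
#'
#' @param crwl,sec `trend_ensemble`s with equal draw counts.
#' @return Probability in \[0, 1\].
#' @export
p_rate_exceed <- function(crwl, sec) {
  a <- crwl$draws_mm_yr
  b <- sec$draws_mm_yr
  if (length(a) != length(b)) stop("ensembles differ in draw count")
  mean(a > b)
}

#' Flooding probability across surface-elevation measurement occasions
#'
#' For each occasion when the wetland surface was measured, compares that
#' surface elevation with the chosen tide level of the same calendar month;
#' the flooding probability is the fraction of occasions where the wetland
#' sits below the tide level.
#'
#' @param wetland A biannual [level_series()] of wetland surface elevations.
#' @param tides Data frame from [tide_triplet()] (monthly).
#' @param condition `"low"`, `"mean"` or `"high"`.
#' @return Probability in \[0, 1\].
#' @export
flooding_probability <- function(wetland, tides, condition = c("low", "mean", "high")) {
  condition <- match.arg(condition)
  stopifnot(inherits(wetland, "level_series"))
  wm <- month_floor(wetland$time)
  tm <- month_floor(tides$time)
  idx <- match(wm, tm)
  keep <- !is.na(idx) & !is.na(wetland$value)
  tide_col <- paste0(condition, "_m")
  tide_val <- tides[[tide_col]][idx[keep]]
  keep2 <- !is.na(tide_val)
  if (sum(keep2) == 0) stop("no overlapping observed months between wetland and tide series")
  mean(wetland$value[keep][keep2] < tide_val[keep2])
}

#' Assign the wetland response category
#'
#' The category is a total function of the two probabilities. With
#' `p_rate`, the probability that corrected water-level rise outpaces
#' surface-elevation change, and `p_flood`, the flooding probability:
#' * `p_rate >= 0.66` (likely outpaced): give-up — drowning complete when
#'   `p_flood >= 0.90`, drowning projected when `p_flood <= 0.10`, drowning
#'   in progress otherwise;
#' * `0.33 <= p_rate < 0.66` (about as likely as not): keep-up — dynamic
#'   equilibrium when `p_flood > 0.10`, stable equilibrium otherwise;
#' * `p_rate < 0.33` (unlikely): catch-up when `p_flood > 0.50`, speed-up
#'   otherwise.
#'
#' The boundary conventions make the seven rules a partition of the unit
#' square.
#'
#' @param p_rate,p_flood Probabilities in \[0, 1\] (vectorized).
#' @return Character vector of categories (see [response_categories]).
#' @export
classify_site <- function(p_rate, p_flood) {
  if (any(p_rate < 0 | p_rate > 1 | p_flood < 0 | p_flood > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1]")
  }
  out <- character(length(p_rate))
  giveup <- p_rate >= 0.66
  keepup <- p_rate >= 0.33 & p_rate < 0.66
  catchy <- p_rate < 0.33
  out[giveup & p_flood >= 0.90] <- response_categories[1]
  out[giveup & p_flood <= 0.10] <- response_categories[3]
  out[giveup & p_flood > 0.10 & p_flood < 0.90] <- response_categories[2]
  out[keepup & p_flood > 0.10] <- response_categories[4]
  out[keepup & p_flood <= 0.10] <- response_categories[5]
  out[catchy & p_flood > 0.50] <- response_categories[6]
  out[catchy & p_flood <= 0.50] <- response_categories[7]
  out
}

#' Surface-elevation-deficit draws for one site
#'
#' Deficit draw i is the corrected water-level trend draw i minus the
#' surface-elevation-change trend draw i; positive values mean the wetland
#' loses elevation relative to the water surface.
#'
#' @param crwl,sec `trend_ensemble`s with equal draw counts.
#' @return Numeric vector of deficit draws in mm/yr.
#' @export
deficit_draws <- function(crwl, sec) {
  a <- crwl$draws_mm_yr
  b <- sec$draws_mm_yr
  if (length(a) != length(b)) stop("ensembles differ in draw count")
  a - b
}

#' Cross-site percentiles of the central surface-elevation deficits
#'
#' @param central_deficits_mm_yr Per-site central (median-of-draws) deficits,
#'   at least 4 sites.
#' @param probs Percentile ranks; default 25th and 50th.
#' @return Named numeric vector of deficit percentiles in mm/yr.
#' @export
cross_site_percentiles <- function(central_deficits_mm_yr,
                                   probs = c(0.25, 0.50)) {
  x <- central_deficits_mm_yr[!is.na(central_deficits_mm_yr)]
  if (length(x) < 4) stop("need at least 4 sites for cross-site percentiles")
  stats::quantile(x, probs = probs, names = TRUE, type = 7)
}

#' Cross-site correlation between water-level and surface-elevation rates
#'
#' Sites whose corrected water-level rate falls outside the central
#' cross-site percentile interval (default 2.5th-97.5th) are excluded as
#' outliers; the Pearson correlation is then computed on the remaining
#' sites and, when an organic-matter fraction is supplied, on the
#' organic-rich subset (fraction > 0.30). Significance is assessed by a
#' seeded permutation of the pairing (the rates across sites carry no
#' serial structure).
#'
#' @param crwl_rates,sec_rates Per-site rates in mm/yr.
#' @param organic_fraction Optional per-site organic-matter fraction.
#' @param trim Lower/upper percentile bounds for the outlier trim.
#' @param organic_threshold Fraction above which a site is organic-rich.
#' @param n_perm Permutations for the p-value; default 10000.
#' @param seed Integer seed.
#' @return List with `all` and (when applicable) `organic`, each holding
#'   `r`, `p_value`, `n`; plus `n_trimmed`.
#' @export
rate_correlation <- function(crwl_rates, sec_rates, organic_fraction = NULL,
                             trim = c(0.025, 0.975), organic_threshold = 0.30,
                             n_perm = 10000, seed = NULL) {
  if (length(crwl_rates) != length(sec_rates)) stop("rate vectors differ in length")
  bounds <- stats::quantile(crwl_rates, probs = trim, type = 7)
  keep <- crwl_rates >= bounds[1] & crwl_rates <= bounds[2]
  if (sum(keep) < 10) stop("fewer than 10 sites remain after trimming")
  one <- function(x, y, sub_seed) {
    r <- stats::cor(x, y)
    r_perm <- with_seed(sub_seed, {
      vapply(seq_len(n_perm),
             function(i) stats::cor(x, sample(y)), 0)
    })
    list(r = r, p_value = (sum(abs(r_perm) >= abs(r)) + 1) / (n_perm + 1),
         n = length(x))
  }
  out <- list(all = one(crwl_rates[keep], sec_rates[keep],
                        derive_seed(seed %||% 0, 1L, "rate_corr")),
              n_trimmed = sum(!keep))
  if (!is.null(organic_fraction)) {
    org <- keep & !is.na(organic_fraction) & organic_fraction > organic_threshold
    if (sum(org) >= 10) {
      out$organic <- one(crwl_rates[org], sec_rates[org],
                         derive_seed(seed %||% 0, 2L, "rate_corr_org"))
    }
  }
  out
}

#' Summary of "safe" versus give-up sites
#'
#' "Safe" sites are those outside the three give-up categories (keep-up,
#' catch-up, speed-up). Reports category shares and median rates for the
#' safe subset versus all sites.
#'
#' @param categories Character vector of per-site categories.
#' @param crwl_rates,sec_rates Per-site central rates in mm/yr.
#' @return List with `shares` (named, sums to 1 over the seven categories),
#'   `safe_share`, `median_crwl_all`, `median_crwl_safe`,
#'   `median_sec_all`, `median_sec_safe`, `n_sites`.
#' @export
safe_site_summary <- function(categories, crwl_rates, sec_rates) {
  n <- length(categories)
  shares <- table(factor(categories, levels = response_categories)) / n
  safe <- !(categories %in% response_categories[1:3])
  list(shares = c(shares),
       safe_share = mean(safe),
       median_crwl_all = stats::median(crwl_rates),
       median_crwl_safe = if (any(safe)) stats::median(crwl_rates[safe]) else NA_real_,
       median_sec_all = stats::median(sec_rates),
       median_sec_safe = if (any(safe)) stats::median(sec_rates[safe]) else NA_real_,
       n_sites = n)
}
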