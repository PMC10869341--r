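#' Run the full wetland-resilience analysis end-to-end
#'
#' Sequences the stages on a monitoring network: quality control and
#' deseasonalization of the water-level records, trend estimation with
#' AR(1) Monte Carlo ensembles, differential vertical-land-motion
#' correction, response classification under each tide condition,
#' surface-elevation-deficit statistics, and (when projection curves are
#' supplied) threshold-crossing analysis. Identical inputs and seed produce
#' identical outputs; per-site randomness uses sub-seeds derived from the
#' master seed, the site index and the stage label.
#'
#' @param network A `synthetic_network` from [generate_network()], or any
#'   list with `stations`, `rwl` (daily series), `sec` (biannual series).
#' @param projections Optional per-location projection curves (long data
#'   frame as produced by [generate_projection_curves()]).
#' @param reference Optional monthly reference geocentric sea-level
#'   [level_series()]; its trend supplies the observed rise rate for the
#'   threshold analysis, and site-vs-reference correlations are computed
#'   when `correlate_reference = TRUE`.
#' @param n_draws Monte Carlo ensemble size; default 10000.
#' @param seed Master integer seed.
#' @param month_threshold,site_threshold Completeness thresholds (see
#'   [apply_month_completeness()], [site_passes()]).
#' @param vlm A [vlm_model()] for applicable sites.
#' @param vlm_mode `"ensemble"` propagates the full correction
#'   distribution through the trend draws; `"central"` subtracts the model
#'   mean from every draw; `"known"` subtracts the per-site rates given in
#'   `known_vlm_rates` (used for validation against synthetic ground truth).
#' @param known_vlm_rates Named numeric vector (mm/yr, by site id) used when
#'   `vlm_mode = "known"`.
#' @param observed_gsl_rate Observed geocentric sea-level rise rate (mm/yr)
#'   for the threshold analysis; defaults to the OLS rate of `reference`.
#' @param deficit_probs Cross-site deficit percentile ranks; default 25th
#'   and 50th.
#' @param correlate_reference Compute per-site correlation with the
#'   reference series (adds surrogate cost).
#' @param out_dir Optional directory where stage outputs are written.
#' @return A list of class `marshpace_run`: `classification` (data frame),
#'   `prep_report`, `deficit_percentiles`, `thresholds`, `scenario_report`,
#'   `summary`, `manifest`.
#' @export
run_pipeline <- function(network, projections = NULL, reference = NULL,
                         n_draws = 10000, seed = 1L,
                         month_threshold = 0.70, site_threshold = 0.70,
                         vlm = vlm_model(),
                         vlm_mode = c("ensemble", "central", "known"),
                         known_vlm_rates = NULL,
                         observed_gsl_rate = NULL,
                         deficit_probs = c(0.25, 0.50),
                         correlate_reference = FALSE,
                         out_dir = NULL) {
  vlm_mode <- match.arg(vlm_mode)
  if (n_draws < 100) stop("ensemble size must be at least 100")
  stations <- network$stations
  window <- NULL
  ref_model <- NULL
  ref_detrended <- NULL
  if (!is.null(reference)) {
    ref_fit <- ols_trend(reference)
    if (is.null(observed_gsl_rate)) observed_gsl_rate <- ref_fit$rate_mm_yr
    if (correlate_reference) {
      ref_model <- fit_ar1(ref_fit$residuals_mm, correct_bias = TRUE)
      ref_detrended <- detrend(reference)
    }
  }

  prep_rows <- list()
  class_rows <- list()
  for (i in seq_len(nrow(stations))) {
    st <- stations[i, ]
    id <- st$site_id
    prep <- prep_site(network$rwl[[id]], month_threshold, site_threshold,
                      window)
    sec_series <- network$sec[[id]]
    sec_obs <- sum(!is.na(sec_series$value))
    sec_pass <- sec_obs / length(sec_series$time) >= site_threshold
    prep_rows[[i]] <- data.frame(
      site_id = id, rwl_passed = prep$passed, sec_passed = sec_pass,
      months_kept = prep$months_kept, months_total = prep$months_total,
      sec_kept = sec_obs, sec_total = length(sec_series$time))
    if (!prep$passed || !sec_pass) next

    # trends + ensembles
    rwl_fit <- ols_trend(prep$deseasonalized)
    rwl_model <- fit_ar1(rwl_fit$residuals_mm, correct_bias = TRUE, extra_dof = 11)
    surr <- simulate_surrogates(rwl_model, length(rwl_fit$time_dec), n_draws,
                                seed = derive_seed(seed, i, "rwl_ens"))
    mon <- as.integer(format(prep$deseasonalized$time, "%m"))
    rwl_p <- trend_p_value(rwl_fit, surr, month = mon)
    rwl_ens <- trend_ensemble(rwl_fit, rwl_model, surrogates = surr,
                              month = mon)

    sec_fit <- ols_trend(sec_series)
    sec_surr <- white_noise_surrogates(sec_fit$residual_sd_mm,
                                       length(sec_fit$time_dec), n_draws,
                                       seed = derive_seed(seed, i, "sec_ens"))
    sec_p <- trend_p_value(sec_fit, sec_surr)
    sec_ens <- trend_ensemble(sec_fit, surrogates = sec_surr)

    # differential VLM correction
    applicable <- requires_correction(st)
    corrections <- switch(
      vlm_mode,
      ensemble = draw_corrections(vlm, n_draws,
                                  seed = derive_seed(seed, i, "vlm"),
                                  applicable = applicable),
      central = rep(if (applicable) vlm$mean_mm_yr else 0, n_draws),
      known = {
        if (is.null(known_vlm_rates) || is.na(known_vlm_rates[id])) {
          stop("vlm_mode = 'known' requires known_vlm_rates for site ", id)
        }
        rep(unname(known_vlm_rates[id]), n_draws)
      })
    crwl_ens <- correct_trend_ensemble(rwl_ens, corrections)
    central_rate <- mean(corrections)
    corrected_monthly <- correct_elevations(prep$monthly, central_rate,
                                            st$survey_year)

    # classification
    tides <- tide_triplet(corrected_monthly, st$tidal_amplitude_m)
    p_rate <- p_rate_exceed(crwl_ens, sec_ens)
    deficits <- deficit_draws(crwl_ens, sec_ens)
    row <- data.frame(
      site_id = id,
      rwl_rate_mm_yr = rwl_ens$rate_mm_yr,
      rwl_p_value = rwl_p,
      crwl_rate_mm_yr = crwl_ens$rate_mm_yr,
      sec_rate_mm_yr = sec_ens$rate_mm_yr,
      sec_p_value = sec_p,
      vlm_applicable = applicable,
      vlm_rate_mm_yr = central_rate,
      p_rate = p_rate,
      deficit_median_mm_yr = stats::median(deficits),
      organic_fraction = st$organic_fraction)
    for (cond in c("low", "mean", "high")) {
      pf <- flooding_probability(sec_series, tides, cond)
      row[[paste0("p_flood_", cond)]] <- pf
      row[[paste0("category_", cond)]] <- classify_site(p_rate, pf)
    }
    if (correlate_reference && !is.null(ref_model)) {
      site_detrended <- detrend(prep$deseasonalized)
      cc <- correlation_p_value(site_detrended, ref_detrended, rwl_model,
                                ref_model, n_draws,
                                seed = derive_seed(seed, i, "ref_corr"))
      row$ref_correlation <- cc$r
      row$ref_corr_p_value <- cc$p_value
    }
    class_rows[[length(class_rows) + 1]] <- row
  }

  prep_report <- do.call(rbind, prep_rows)
  if (length(class_rows) == 0) {
    stop("no site passed the completeness filters")
  }
  classification <- do.call(rbind, c(class_rows, list(make.row.names = FALSE)))

  deficit_pct <- cross_site_percentiles(classification$deficit_median_mm_yr,
                                        probs = deficit_probs)
  thresholds <- if (!is.null(observed_gsl_rate)) {
    thresholds_from_deficits(observed_gsl_rate, deficit_pct)
  } else NULL

  scen_report <- NULL
  if (!is.null(projections) && !is.null(thresholds)) {
    scen_report <- scenario_report(average_locations(projections), thresholds)
  }

  summary <- lapply(c("low", "mean", "high"), function(cond) {
    safe_site_summary(classification[[paste0("category_", cond)]],
                      classification$crwl_rate_mm_yr,
                      classification$sec_rate_mm_yr)
  })
  names(summary) <- c("low", "mean", "high")

  manifest <- list(
    seed = seed, n_draws = n_draws, vlm_mode = vlm_mode,
    month_threshold = month_threshold, site_threshold = site_threshold,
    observed_gsl_rate_mm_yr = observed_gsl_rate,
    n_sites_input = nrow(stations),
    n_sites_classified = nrow(classification),
    n_sites_dropped = nrow(stations) - nrow(classification))

  run <- structure(
    list(classification = classification, prep_report = prep_report,
         deficit_percentiles = deficit_pct, thresholds = thresholds,
         scenario_report = scen_report, summary = summary,
         manifest = manifest),
    class = "marshpace_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# Persist the stage outputs of a run as plain-text files.
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$classification,
                   file.path(out_dir, "classification.csv"), row.names = FALSE)
  utils::write.csv(run$prep_report,
                   file.path(out_dir, "prep_report.csv"), row.names = FALSE)
  if (!is.null(run$thresholds)) {
    utils::write.csv(run$thresholds, file.path(out_dir, "thresholds.csv"),
                     row.names = FALSE)
  }
  if (!is.null(run$scenario_report)) {
    utils::write.csv(run$scenario_report,
                     file.path(out_dir, "scenario_report.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(manifest = run$manifest,
         deficit_percentiles = as.list(run$deficit_percentiles),
         summary = run$summary),
    file.path(out_dir, "run_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.marshpace_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<marshpace_run> %d/%d sites classified (seed %d, %d draws)\n",
              m$n_sites_classified, m$n_sites_input, m$seed, m$n_draws))
  for (cond in names(x$summary)) {
    s <- x$summary[[cond]]
    cat(sprintf("  %s tide: %.0f%% give-up, %.0f%% safe\n", cond,
                100 * (1 - s$safe_share), 100 * s$safe_share))
  }
  if (!is.null(x$deficit_percentiles)) {
    cat("  deficit percentiles (mm/yr):",
        paste(sprintf("%s = %.1f", names(x$deficit_percentiles),
                      x$deficit_percentiles), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Human-readable report of a completed run
#'
#' Formats category shares per tide condition, the deficit distribution
#' with highlighted percentiles, and the scenario crossing-year table.
#'
#' @param run A `marshpace_run`.
#' @return Character vector of report lines (also printed).
#' @export
pipeline_report <- function(run) {
  stopifnot(inherits(run, "marshpace_run"))
  lines <- c(sprintf("Sites classified: %d of %d",
                     run$manifest$n_sites_classified,
                     run$manifest$n_sites_input))
  for (cond in names(run$summary)) {
    s <- run$summary[[cond]]
    shares <- sprintf("  %-32s %5.1f%%", names(s$shares), 100 * s$shares)
    lines <- c(lines, sprintf("%s tide condition:", toupper(cond)), shares,
               sprintf("  safe share: %.1f%%", 100 * s$safe_share))
  }
  if (!is.null(run$deficit_percentiles)) {
    lines <- c(lines, "Surface-elevation deficit percentiles (mm/yr):",
               sprintf("  %s: %.2f", names(run$deficit_percentiles),
                       run$deficit_percentiles))
  }
  if (!is.null(run$scenario_report)) {
    sr <- run$scenario_report
    lines <- c(lines, "Projected threshold crossings:",
               sprintf("  %s [%s band] threshold %.1f mm/yr -> %s",
                       sr$scenario, sr$band, sr$threshold_mm_yr,
                       ifelse(is.na(sr$crossing_year), "not by end of grid",
                              as.character(sr$crossing_year))))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
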