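#' Write a synthetic network to plain-text fixture files
#'
#' Writes the station table (`stations.csv`), one CSV per water-level and
#' surface-elevation series under `series/` (columns `timestamp`,
#' `elevation_m`; ISO-8601 dates; missing values left empty), and the
#' ground-truth table (`ground_truth.json`). The files round-trip losslessly
#' through [read_fixtures()].
#'
#' @param network A `synthetic_network` from [generate_network()].
#' @param directory Target directory (created if absent).
#' @param overwrite Allow writing over an existing fixture set.
#' @return Invisibly, the vector of files written.
#' @export
write_fixtures <- function(network, directory, overwrite = FALSE) {
  stopifnot(inherits(network, "synthetic_network"))
  if (file.exists(file.path(directory, "stations.csv")) && !overwrite) {
    stop("fixture set already exists in ", directory,
         " (use overwrite = TRUE)")
  }
  dir.create(file.path(directory, "series"), recursive = TRUE,
             showWarnings = FALSE)
  files <- file.path(directory, "stations.csv")
  utils::write.csv(network$stations, files, row.names = FALSE)

  write_series <- function(s, path) {
    df <- data.frame(timestamp = format(s$time, "%Y-%m-%d"),
                     elevation_m = sprintf_na(s$value))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    path
  }
  for (id in names(network$rwl)) {
    files <- c(files, write_series(network$rwl[[id]],
                                   file.path(directory, "series",
                                             paste0("rwl_", id, ".csv"))))
  }
  for (id in names(network$sec)) {
    files <- c(files, write_series(network$sec[[id]],
                                   file.path(directory, "series",
                                             paste0("sec_", id, ".csv"))))
  }
  truth_path <- file.path(directory, "ground_truth.json")
  jsonlite::write_json(network$truth, truth_path, digits = NA, na = "null")
  files <- c(files, truth_path)
  invisible(files)
}

sprintf_na <- function(x) ifelse(is.na(x), "", sprintf("%.15g", x))

#' Read a fixture set written by [write_fixtures()]
#'
#' @param directory Fixture directory.
#' @return A list with `stations`, `rwl`, `sec`, `truth` mirroring the
#'   structure of a `synthetic_network` (without the config).
#' @export
read_fixtures <- function(directory) {
  stations <- utils::read.csv(file.path(directory, "stations.csv"),
                              colClasses = c(site_id = "character"))
  read_series <- function(path, id, cadence) {
    df <- utils::read.csv(path, colClasses = c("character", "numeric"))
    comp <- if (cadence == "biannual") as.numeric(!is.na(df$elevation_m)) else NULL
    level_series(id, as.Date(df$timestamp), df$elevation_m, cadence,
                 completeness = comp)
  }
  rwl <- lapply(stations$site_id, function(id) {
    read_series(file.path(directory, "series", paste0("rwl_", id, ".csv")),
                id, "daily")
  })
  sec <- lapply(stations$site_id, function(id) {
    read_series(file.path(directory, "series", paste0("sec_", id, ".csv")),
                id, "biannual")
  })
  names(rwl) <- names(sec) <- stations$site_id
  truth_path <- file.path(directory, "ground_truth.json")
  truth <- if (file.exists(truth_path)) {
    as.data.frame(jsonlite::fromJSON(truth_path))
  } else NULL
  list(stations = stations, rwl = rwl, sec = sec, truth = truth)
}

#' Write projection curves to CSV
#'
#' @param curves Data frame from [generate_projection_curves()] (columns
#'   `scenario`, `location_id`, `year`, `rate_mm_yr`, `sigma_mm_yr`).
#' @param path Output CSV path.
#' @export
write_projections <- function(curves, path) {
  utils::write.csv(curves[, c("scenario", "year", "rate_mm_yr",
                              "sigma_mm_yr", "location_id")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read projection curves from CSV
#'
#' @param path CSV path with columns `scenario`, `year`, `rate_mm_yr`,
#'   `sigma_mm_yr`, `location_id`.
#' @return Data frame in the layout [average_locations()] expects.
#' @export
read_projections <- function(path) {
  utils::read.csv(path, colClasses = c(scenario = "character",
                                       location_id = "character"))
}
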