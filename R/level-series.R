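#' Construct a level series
#'
#' A `level_series` holds a timestamped elevation record (water surface or
#' wetland surface) on a common vertical datum, together with the
#' completeness bookkeeping needed by the quality-control filters. All
#' elevations are stored in meters; rates are only expressed in mm/yr at
#' reporting boundaries.
#'
#' @param site_id Character scalar identifying the monitoring site.
#' @param time Timestamps. `POSIXct` for hourly cadence, `Date` otherwise
#'   (first of month for monthly series).
#' @param value Numeric elevations in meters; `NA` marks a missing period.
#' @param cadence One of `"hourly"`, `"daily"`, `"monthly"`, `"biannual"`.
#' @param completeness Optional per-period fraction in \[0, 1\] recording how
#'   much of the underlying finer-cadence record contributed to each value.
#'
#' @return An object of class `level_series`.
#' @export
level_series <- function(site_id, time, value,
                         cadence = c("daily", "hourly", "monthly", "biannual"),
                         completeness = NULL) {
  cadence <- match.arg(cadence)
  if (length(time) != length(value)) {
    stop("`time` and `value` must have equal length")
  }
  if (cadence == "hourly") {
    if (!inherits(time, "POSIXct")) stop("hourly series require POSIXct timestamps")
  } else {
    time <- as.Date(time)
  }
  if (is.unsorted(as.numeric(time), strictly = TRUE)) {
    stop("timestamps must be strictly increasing")
  }
  if (any(is.infinite(value))) stop("values must be finite where present")
  if (!is.null(completeness)) {
    if (length(completeness) != length(value)) {
      stop("`completeness` must match the series length")
    }
    if (any(completeness < 0 | completeness > 1, na.rm = TRUE)) {
      stop("completeness fractions must lie in [0, 1]")
    }
  }
  structure(
    list(site_id = as.character(site_id), cadence = cadence,
         time = time, value = as.numeric(value), completeness = completeness),
    class = "level_series"
  )
}

#' @export
print.level_series <- function(x, ...) {
  n_obs <- sum(!is.na(x$value))
  cat(sprintf("<level_series> site %s, %s cadence, %d stamps (%d observed), %s to %s\n",
              x$site_id, x$cadence, length(x$time), n_obs,
              format(min(x$time)), format(max(x$time))))
  invisible(x)
}

#' @export
length.level_series <- function(x) length(x$time)

#' Convert timestamps to decimal years
#'
#' Maps a `Date` (or `POSIXct`) to a continuous year coordinate: the year plus
#' the mid-day-corrected fraction of the year elapsed, honoring leap years.
#' Used as the regression abscissa throughout, so that slopes of elevation
#' (m) against `decimal_year` are in m/yr.
#'
#' @param time `Date` or `POSIXct` vector.
#' @return Numeric vector of decimal years.
#' @export
decimal_year <- function(time) {
  d <- as.Date(time)
  yr <- as.integer(format(d, "%Y"))
  jan1 <- as.Date(paste0(yr, "-01-01"))
  next_jan1 <- as.Date(paste0(yr + 1L, "-01-01"))
  ndays <- as.numeric(next_jan1 - jan1)
  yr + (as.numeric(d - jan1) + 0.5) / ndays
}

# First day of the calendar month containing each date.
month_floor <- function(d) as.Date(format(as.Date(d), "%Y-%m-01"))

# Number of days in the calendar month containing each date (leap-aware).
days_in_month <- function(d) {
  start <- month_floor(d)
  nxt <- month_floor(start + 31)
  as.numeric(nxt - start)
}

# Sequence of first-of-month dates covering [from, to].
month_seq <- function(from, to) {
  seq(month_floor(from), month_floor(to), by = "month")
}

# Derive a deterministic sub-seed from a master seed, a site index and a
# stage label. The rule is a fixed integer hash so identical (seed, site,
# stage) triples always map to the same stream, independently of the order
# in which sites are processed.
derive_seed <- function(master_seed, site_index = 0L, stage = "") {
  stage_code <- if (nzchar(stage)) {
    sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 99991L
  } else 0L
  as.integer((as.numeric(master_seed) * 10007 + site_index * 101 +
                stage_code) %% 2147483647)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
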