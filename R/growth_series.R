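#' Daily growth-rate series for one growing season
#'
#' Container for the daily integral growth rates of one growing season, the
#' environmental forcing of the simulator. In the field these come from the
#' environmental block of the Vaganov-Shashkin (VS) model: the daily integral
#' growth rate is the minimum of the temperature- and moisture-limited
#' partial rates weighted by photoperiod, a relative value in \[0, 1\].
#' Computing it from climate data is outside the scope of this package; the
#' series is consumed ready-made (or generated by [gen_growth_series()]).
#'
#' @param year calendar year (may be `NA` for synthetic/averaged seasons).
#' @param doy_start 1-based day of year on which the season starts.
#' @param doy_end day of year on which the season ends; must exceed
#'   `doy_start`.
#' @param rates numeric vector of daily rates in \[0, 1\], one per day from
#'   `doy_start` to `doy_end` inclusive.
#' @return An object of class `growth_series`.
#' @examples
#' gs <- growth_series(2001, 127, 285, rep(0.5, 159))
#' season_length(gs)
#' @export
growth_series <- function(year, doy_start, doy_end, rates) {
  gs <- structure(
    list(year = as.integer(year), doy_start = as.integer(doy_start),
         doy_end = as.integer(doy_end), rates = as.numeric(rates)),
    class = "growth_series"
  )
  validate_growth_series(gs)
  gs
}

#' Validate a growth series
#'
#' Enforces the container invariants: `doy_start < doy_end`, one rate per
#' day, every rate finite and in \[0, 1\].
#'
#' @param gs a `growth_series` object.
#' @param what label used in error messages (e.g. a year).
#' @return `gs`, invisibly.
#' @export
validate_growth_series <- function(gs, what = gs$year) {
  lab <- if (is.na(what) || is.null(what)) "series" else paste("year", what)
  if (is.na(gs$doy_start) || is.na(gs$doy_end) || gs$doy_start >= gs$doy_end) {
    stop(lab, ": doy_start must be < doy_end", call. = FALSE)
  }
  n_exp <- gs$doy_end - gs$doy_start + 1L
  if (length(gs$rates) != n_exp) {
    stop(lab, ": expected ", n_exp, " daily rates, got ", length(gs$rates),
         call. = FALSE)
  }
  bad <- which(!is.finite(gs$rates) | gs$rates < 0 | gs$rates > 1)
  if (length(bad)) {
    stop(lab, ", day-of-year ", gs$doy_start + bad[1L] - 1L,
         ": rate ", gs$rates[bad[1L]], " outside [0, 1]", call. = FALSE)
  }
  invisible(gs)
}

#' Season length in days
#'
#' `doy_end - doy_start`, the length of the environmental growing season.
#'
#' @param gs a `growth_series`.
#' @return a single number of days.
#' @export
season_length <- function(gs) gs$doy_end - gs$doy_start

#' @export
print.growth_series <- function(x, ...) {
  cat(sprintf("Growth-rate series (%s): DOY %d-%d, %d days, mean rate %.3f\n",
              ifelse(is.na(x$year), "average season", x$year),
              x$doy_start, x$doy_end, length(x$rates), mean(x$rates)))
  invisible(x)
}

#' Load daily growth-rate series from CSV
#'
#' Reads a comma-separated file with header `year,doy,rate` (optionally also
#' `doy_start,doy_end`, constant within a year) and returns one
#' [growth_series()] per year. Days must be contiguous within each year;
#' season bounds default to the first/last day present.
#'
#' @param path path to the CSV file.
#' @return a named list of `growth_series`, keyed by year.
#' @seealso [write_growth_series()] for the inverse.
#' @export
load_growth_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "doy", "rate")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (yr in sort(unique(df$year))) {
    sub <- df[df$year == yr, , drop = FALSE]
    sub <- sub[order(sub$doy), , drop = FALSE]
    if (any(diff(sub$doy) != 1L)) {
      gap <- sub$doy[which(diff(sub$doy) != 1L)[1L]]
      stop("year ", yr, ": non-contiguous day-of-year after day ", gap,
           call. = FALSE)
    }
    ds <- if ("doy_start" %in% names(df)) sub$doy_start[1L] else min(sub$doy)
    de <- if ("doy_end" %in% names(df)) sub$doy_end[1L] else max(sub$doy)
    if (ds != min(sub$doy) || de != max(sub$doy)) {
      stop("year ", yr, ": declared season bounds do not match days present",
           call. = FALSE)
    }
    out[[as.character(yr)]] <- growth_series(yr, ds, de, sub$rate)
  }
  out
}

#' Write growth-rate series to CSV
#'
#' Writes a list of [growth_series()] in the dialect read by
#' [load_growth_series()] (`year,doy,rate`).
#'
#' @param series_set a list of `growth_series`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_growth_series <- function(series_set, path) {
  if (inherits(series_set, "growth_series")) series_set <- list(series_set)
  rows <- lapply(series_set, function(gs) {
    data.frame(year = gs$year, doy = gs$doy_start:gs$doy_end, rate = gs$rates)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summary statistics of a season's growth-rate curve
#'
#' The six distributional statistics of the daily rates that drive the
#' seasonal inhibitor-supply regression: standard deviation (n-1
#' denominator), median, median absolute deviation, minimum, maximum and the
#' moment coefficient of skewness.
#'
#' By default mad is the raw median of absolute deviations from the median
#' (no normal-consistency scaling; set `mad_scaled = TRUE` in the parameter
#' set for the 1.4826 convention) and skewness is the population moment
#' coefficient `g1 = m3 / m2^1.5`, defined as 0 for a constant sequence.
#'
#' @param series a `growth_series`.
#' @param params a [cambium_params()] object (controls the mad convention).
#' @return named numeric vector with elements `sd`, `median`, `mad`, `min`,
#'   `max`, `skew`.
#' @examples
#' gs <- growth_series(NA, 1, 5, c(0.2, 0.4, 0.6, 0.4, 0.2))
#' season_stats(gs)
#' @export
season_stats <- function(series, params = cambium_params()) {
  x <- series$rates
  if (length(x) == 0L) stop("empty series", call. = FALSE)
  med <- stats::median(x)
  m2 <- mean((x - mean(x))^2)
  skew <- if (m2 == 0) 0 else mean((x - mean(x))^3) / m2^1.5
  mad_raw <- stats::median(abs(x - med))
  c(sd = if (length(x) > 1L) stats::sd(x) else 0,
    median = med,
    mad = if (isTRUE(params$mad_scaled)) 1.4826 * mad_raw else mad_raw,
    min = min(x), max = max(x), skew = skew)
}

#' Detect a stress window before a division day
#'
#' A division is stress-flagged when the daily integral growth rate has
#' consistently decreased for three days or more immediately before the
#' division: the rates must strictly decrease on each of at least three
#' consecutive day-to-day steps ending at day `t`.
#'
#' @param series a `growth_series`.
#' @param t 1-based day within the season on which the division occurs.
#' @return `TRUE` if the trailing window is strictly decreasing, else
#'   `FALSE`. Days earlier than the fourth day of the season return `FALSE`
#'   (insufficient history).
#' @export
detect_stress_window <- function(series, t) {
  t <- as.integer(t)
  if (t < 4L || t > length(series$rates)) return(FALSE)
  w <- series$rates[(t - 3L):t]
  all(diff(w) < 0)
}

#' Build an average growth season
#'
#' Collapses several seasons into one synthetic "average growth season":
#' the season bounds are the rounded means of the per-year bounds and the
#' rate on each day of year is the mean over all years whose season covers
#' that day. Averaging aligns by calendar day of year, matching how average
#' season bounds are reported.
#'
#' @param series_set a non-empty list of `growth_series`.
#' @return a `growth_series` with `year = NA`.
#' @export
build_average_season <- function(series_set) {
  series_set <- unname(series_set)
  if (length(series_set) == 0L) stop("empty series collection", call. = FALSE)
  ds <- as.integer(round(mean(vapply(series_set, `[[`, 1, "doy_start"))))
  de <- as.integer(round(mean(vapply(series_set, `[[`, 1, "doy_end"))))
  doy <- ds:de
  rates <- vapply(doy, function(d) {
    vals <- unlist(lapply(series_set, function(gs) {
      if (d >= gs$doy_start && d <= gs$doy_end) {
        gs$rates[d - gs$doy_start + 1L]
      } else NULL
    }))
    if (length(vals) == 0L) {
      stop("day-of-year ", d, " covered by no input season", call. = FALSE)
    }
    mean(vals)
  }, numeric(1))
  growth_series(NA, ds, de, rates)
}
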