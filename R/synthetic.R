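#' Configuration for synthetic growth-rate fixtures
#'
#' Describes the synthetic seasonal forcing the generator emulates: a
#' bell-shaped daily growth-rate curve over the growing season (onset and
#' offset around days of year 127 and 285), AR(1) weather noise, and
#' occasional multi-day strictly-declining "stress dips" such as drought
#' spells produce in cold semi-arid sites. Year-to-year variation comes from
#' a per-year peak drawn uniformly from `peak_range`, the noise, and the
#' random dip placement. The defaults are the package's standing study
#' conditions.
#'
#' @param n_years number of seasons.
#' @param start_year calendar year of the first season.
#' @param doy_start,doy_end season bounds (day of year).
#' @param peak_range range of the per-year bell peak rate.
#' @param bell_exponent range of the per-year exponent of the sinusoidal
#'   bell (a scalar fixes it); higher exponents give narrower, more peaked
#'   seasons.
#' @param floor_range range of the per-year baseline rate: inside the
#'   detected growing season the integral rate stays small but positive, and
#'   its seasonal minimum varies between years.
#' @param noise_sigma marginal standard deviation of the AR(1) noise.
#' @param noise_rho lag-1 autocorrelation of the noise.
#' @param n_dips stress dips per season.
#' @param dip_depth_range relative depth range of a dip.
#' @param dip_steps_range range of strictly-declining day-to-day steps per
#'   dip (at least 3, so the stress detector can fire inside a dip).
#' @param regression the true [supply_model()] generating seasonal supplies.
#' @param params the true [cambium_params()].
#' @param supply_noise_sd standard deviation of Gaussian noise added to the
#'   true supplies (`0` for noise-free fixtures); `supply_noise_frac`, if
#'   non-`NULL`, overrides it as a fraction of the mean true supply.
#' @param supply_noise_frac optional noise level as a fraction of the mean
#'   supply.
#' @param production_noise `"none"`, or `"poisson"` for Poisson jitter of
#'   the observed production around the simulated value.
#' @param seed integer seed fixing all randomness of the fixture.
#' @return an object of class `fixture_config`.
#' @export
fixture_config <- function(n_years = 40, start_year = 1963,
                           doy_start = 127, doy_end = 285,
                           peak_range = c(0.55, 1.0),
                           bell_exponent = c(0.7, 2.2),
                           floor_range = c(0.003, 0.08),
                           noise_sigma = 0.05, noise_rho = 0.6,
                           n_dips = 2, dip_depth_range = c(0.3, 0.7),
                           dip_steps_range = c(3, 6),
                           regression = supply_model(),
                           params = cambium_params(),
                           supply_noise_sd = 0, supply_noise_frac = NULL,
                           production_noise = c("none", "poisson"),
                           seed = 1) {
  if (doy_start >= doy_end) stop("doy_start must be < doy_end", call. = FALSE)
  if (min(dip_steps_range) < 3) {
    stop("stress dips need at least 3 declining steps", call. = FALSE)
  }
  structure(
    list(n_years = as.integer(n_years), start_year = as.integer(start_year),
         doy_start = as.integer(doy_start), doy_end = as.integer(doy_end),
         peak_range = range(peak_range),
         bell_exponent = range(bell_exponent),
         floor_range = range(floor_range),
         noise_sigma = noise_sigma, noise_rho = noise_rho,
         n_dips = as.integer(n_dips), dip_depth_range = dip_depth_range,
         dip_steps_range = as.integer(dip_steps_range),
         regression = regression, params = params,
         supply_noise_sd = supply_noise_sd,
         supply_noise_frac = supply_noise_frac,
         production_noise = match.arg(production_noise),
         seed = as.integer(seed)),
    class = "fixture_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# One synthetic season (no RNG handling; caller controls the stream).
gen_one_season <- function(config, year) {
  n <- config$doy_end - config$doy_start + 1L
  x <- seq(0, 1, length.out = n)
  peak <- stats::runif(1, config$peak_range[1], config$peak_range[2])
  expo <- stats::runif(1, config$bell_exponent[1], config$bell_exponent[2])
  floor_r <- stats::runif(1, config$floor_range[1], config$floor_range[2])
  base <- floor_r + peak * sin(pi * x)^expo
  e <- numeric(n)
  innov_sd <- config$noise_sigma * sqrt(1 - config$noise_rho^2)
  z <- stats::rnorm(n)
  for (t in seq_len(n)) {
    e[t] <- if (t == 1L) config$noise_sigma * z[1L]
            else config$noise_rho * e[t - 1L] + innov_sd * z[t]
  }
  r <- pmin(pmax(base + e, 0), 1)
  dips <- NULL
  if (config$n_dips > 0L) {
    lo <- max(5L, floor(0.15 * n)); hi <- min(n - 8L, ceiling(0.85 * n))
    # one dip per equal segment of the eligible window, so dips never overlap
    edges <- floor(seq(lo, hi, length.out = config$n_dips + 1L))
    starts <- vapply(seq_len(config$n_dips), function(j) {
      top_end <- max(edges[j], edges[j + 1L] - 8L)
      sample(edges[j]:top_end, 1L)
    }, integer(1))
    dip_steps <- integer(config$n_dips)
    for (j in seq_along(starts)) {
      s <- starts[j]
      steps <- sample(config$dip_steps_range[1]:config$dip_steps_range[2], 1)
      depth <- stats::runif(1, config$dip_depth_range[1],
                            config$dip_depth_range[2])
      steps <- min(steps, n - s)
      dip_steps[j] <- steps
      top <- max(r[s], 0.1)
      r[s] <- top
      for (k in seq_len(steps)) {
        r[s + k] <- top * (1 - depth * k / steps)
      }
    }
    dips <- data.frame(start_day = starts, steps = dip_steps)
    r <- pmin(pmax(r, 0), 1)
  }
  gs <- growth_series(year, config$doy_start, config$doy_end, r)
  attr(gs, "dips") <- dips   # day-within-season of each injected stress dip
  gs
}

#' Generate synthetic daily growth-rate series
#'
#' Draws `n_years` seasons from the configured bell + AR(1) + stress-dip
#' model. All randomness is fixed by `config$seed`: the same configuration
#' always yields the same series.
#'
#' @param config a [fixture_config()].
#' @return named list of [growth_series()] keyed by year.
#' @examples
#' ss <- gen_growth_series(fixture_config(n_years = 2, seed = 7))
#' sapply(ss, function(s) max(s$rates))
#' @export
gen_growth_series <- function(config = fixture_config()) {
  with_seed(config$seed, {
    years <- config$start_year + seq_len(config$n_years) - 1L
    out <- lapply(years, function(y) gen_one_season(config, y))
    names(out) <- as.character(years)
    out
  })
}

#' Generate a full study fixture with known ground truth
#'
#' Builds everything the calibration workflow consumes, with the truth
#' recorded: growth-rate series, per-season true supplies from the true
#' regression applied to the generated statistics (plus optional Gaussian
#' noise), and observed productions simulated under the true parameter set
#' (plus optional Poisson jitter).
#'
#' @param config a [fixture_config()].
#' @return list with `series` (list of `growth_series`), `observed` (data
#'   frame `year`, `cells`) and `truth` (a list recording the generating
#'   regression and parameters, the noise-free supplies `supply_clean`, the
#'   supplies actually used `supply`, the noise level, and the noise-free
#'   simulated productions `production_clean`).
#' @export
gen_study_fixture <- function(config = fixture_config()) {
  series <- gen_growth_series(config)
  params <- config$params
  stats_list <- lapply(series, season_stats, params = params)
  skew <- vapply(stats_list, `[[`, numeric(1), "skew")
  skew_prev <- c(params$skew_default, skew[-length(skew)])
  clean <- vapply(seq_along(series), function(k) {
    as.numeric(predict_supply(stats_list[[k]], skew_prev[k],
                              config$regression))
  }, numeric(1))
  with_seed(config$seed + 1L, {
    noise_sd <- if (!is.null(config$supply_noise_frac)) {
      config$supply_noise_frac * mean(clean)
    } else config$supply_noise_sd
    supply <- clean + if (noise_sd > 0) stats::rnorm(length(clean),
                                                    sd = noise_sd) else 0
    sim_prod <- function(s) vapply(seq_along(series), function(k) {
      suppressWarnings(
        simulate_season(series[[k]], params, s[k])$production)
    }, integer(1))
    prod_used <- sim_prod(supply)          # from the supplies actually used
    prod_clean <- if (noise_sd > 0) sim_prod(clean) else prod_used
    observed <- if (config$production_noise == "poisson") {
      stats::rpois(length(prod_used), lambda = pmax(prod_used, 0.01))
    } else prod_used
    years <- vapply(series, `[[`, integer(1), "year")
    list(series = series,
         observed = data.frame(year = years, cells = observed),
         truth = list(regression = config$regression, params = params,
                      supply_clean = clean,
                      supply = stats::setNames(supply, years),
                      supply_noise_sd = noise_sd,
                      skew_prev = skew_prev,
                      production_clean = prod_clean))
  })
}
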