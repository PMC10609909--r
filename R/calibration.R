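#' Infer the seasonal inhibitor supply from observed cell production
#'
#' Inverts the season simulator: finds, by monotone bisection, the smallest
#' supply (to a relative tolerance of 1e-4) whose simulated production
#' equals the observed target. Production is non-decreasing in supply, so
#' the upper bracket is grown by doubling until the target is reached; if
#' production plateaus below the target (short season), the supply achieving
#' the closest production is returned with `attained = FALSE`.
#'
#' @param series a [growth_series()].
#' @param params a [cambium_params()] object.
#' @param target observed cell production (non-negative integer).
#' @param tol relative bisection tolerance on the supply.
#' @return list with `supply`, `production` (simulated at that supply) and
#'   `attained` (logical).
#' @export
infer_supply_for_production <- function(series, params = cambium_params(),
                                        target, tol = 1e-4) {
  if (!is.finite(target) || target < 0) {
    stop("target production must be a finite non-negative number",
         call. = FALSE)
  }
  target <- as.integer(round(target))
  prod_at <- function(s) {
    suppressWarnings(simulate_season(series, params, s)$production)
  }
  if (target == 0L) {
    return(list(supply = 0, production = 0L, attained = TRUE))
  }
  # grow the upper bracket by doubling; stop early once production stops
  # responding (in the season-length-limited regime extra supply no longer
  # converts to exports, so the target has plateaued out of reach)
  upper <- max(1, 2 * params$C_min * params$D_init)
  p_upper <- prod_at(upper)
  best_s <- upper; best_p <- p_upper
  stalls <- 0L; n_doubles <- 0L
  while (p_upper < target && n_doubles < 30L && stalls < 2L) {
    upper <- upper * 2
    n_doubles <- n_doubles + 1L
    p_prev <- p_upper
    p_upper <- prod_at(upper)
    if (p_upper > best_p) { best_p <- p_upper; best_s <- upper }
    stalls <- if (p_upper <= p_prev) stalls + 1L else 0L
  }
  if (p_upper < target) {
    return(list(supply = best_s, production = best_p, attained = FALSE))
  }
  lower <- 0
  while ((upper - lower) > tol * max(upper, 1)) {
    mid <- (lower + upper) / 2
    if (prod_at(mid) >= target) upper <- mid else lower <- mid
  }
  p <- prod_at(upper)
  if (p == target) {
    return(list(supply = upper, production = p, attained = TRUE))
  }
  # production is globally increasing but locally jagged: a marginal cell
  # that divides rather than exporting strands its daughters in the row at
  # season end, so the bisection boundary can overshoot the target by a
  # cell or two. Scan forward for the equality plateau.
  best_s <- upper; best_p <- p
  # fine ascending sweep below the boundary first (narrow islands hide in
  # the jagged staircase), then a coarser geometric sweep above it for
  # targets that only occur on the season-length-limited falling branch
  scan <- c(seq(0.75 * upper, upper, length.out = 60L),
            exp(seq(log(upper), log(max(4 * upper, upper + 4)),
                    length.out = 70L))[-1L])
  for (s in scan) {
    ps <- prod_at(s)
    if (ps == target) {
      return(list(supply = s, production = ps, attained = TRUE))
    }
    if (abs(ps - target) < abs(best_p - target)) {
      best_s <- s; best_p <- ps
    }
  }
  list(supply = best_s, production = best_p, attained = FALSE)
}

#' Multi-year reconstruction of cell production
#'
#' Applies the season-invariant parameters across a set of years: for each
#' year the supply is predicted from the growth-rate summary statistics via
#' the regression model (the previous season's skewness enters when the
#' previous year is present, otherwise the configured default is used with a
#' warning), and the season is simulated. Years with a non-positive
#' predicted supply produce 0 cells with a warning.
#'
#' @param series_set named list of [growth_series()] keyed by year.
#' @param params a [cambium_params()] object.
#' @param model a [supply_model()].
#' @return data frame with one row per year: `year`, `supply`,
#'   `supply_nonpositive`, `production`, `simulated_season_length`,
#'   `env_season_length`, `termination_reason`.
#' @export
run_multi_year <- function(series_set, params = cambium_params(),
                           model = supply_model()) {
  if (length(series_set) == 0L) stop("no seasons supplied", call. = FALSE)
  years <- vapply(series_set, `[[`, integer(1), "year")
  ord <- order(years)
  series_set <- series_set[ord]; years <- years[ord]
  stats_list <- lapply(series_set, season_stats, params = params)
  rows <- vector("list", length(years))
  for (k in seq_along(years)) {
    prev <- which(years == years[k] - 1L)
    skew_prev <- if (length(prev) == 1L) {
      stats_list[[prev]][["skew"]]
    } else {
      warning("year ", years[k], ": previous season absent; using default ",
              "skewness ", params$skew_default, call. = FALSE)
      params$skew_default
    }
    s <- predict_supply(stats_list[[k]], skew_prev, model)
    flagged <- isTRUE(attr(s, "nonpositive"))
    if (flagged) {
      warning("year ", years[k], ": non-positive predicted supply (",
              signif(as.numeric(s), 4), "); production set to 0",
              call. = FALSE)
    }
    res <- suppressWarnings(
      simulate_season(series_set[[k]], params, as.numeric(s)))
    rows[[k]] <- data.frame(
      year = years[k], supply = as.numeric(s), supply_nonpositive = flagged,
      production = res$production,
      simulated_season_length = res$simulated_season_length,
      env_season_length = res$env_season_length,
      termination_reason = res$termination_reason,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Calibration / verification goodness of fit
#'
#' Computes the coefficient of determination — defined as the squared
#' Pearson correlation between observed and simulated values — within the
#' calibration and verification year sets, plus the overall Pearson
#' correlation.
#'
#' @param observed,simulated numeric vectors aligned with `years`.
#' @param years the years of each observation.
#' @param split list with elements `calibration` and `verification`, each a
#'   vector of years (at least 3 per side).
#' @return list with `R2_calibration`, `R2_verification`, `r_overall` and
#'   the per-side sample sizes.
#' @export
split_goodness <- function(observed, simulated, years, split) {
  stopifnot(length(observed) == length(simulated),
            length(observed) == length(years))
  side <- function(name) {
    keep <- years %in% split[[name]]
    if (sum(keep) < 3L) {
      stop(name, " side has fewer than 3 years", call. = FALSE)
    }
    o <- observed[keep]; s <- simulated[keep]
    if (stats::sd(o) == 0 || stats::sd(s) == 0) {
      stop(name, " side is degenerate (constant series)", call. = FALSE)
    }
    stats::cor(o, s)^2
  }
  list(R2_calibration = side("calibration"),
       R2_verification = side("verification"),
       r_overall = stats::cor(observed, simulated),
       n_calibration = sum(years %in% split$calibration),
       n_verification = sum(years %in% split$verification))
}

#' Tune parameters on the average growth season
#'
#' Adjusts a subset of the model parameters (optionally including the
#' supply) so that the average season reproduces target values of mean cell
#' production and first-division day. The objective is
#' `w1 * (production - target)^2 + w2 * (first_division_day - target)^2`,
#' minimised derivative-free: a deterministic coarse grid over the bounds
#' picks start points, refined by Nelder-Mead (bound violations penalised);
#' a single free parameter uses golden-section search on the interval.
#'
#' @param avg a [growth_series()], typically from [build_average_season()].
#' @param targets list with elements `production` (cells) and, optionally,
#'   `first_division_day` (days from season start).
#' @param free character vector of free parameter names (fields of
#'   [cambium_params()], or `"supply"`).
#' @param lower,upper named numeric bounds for each free parameter.
#' @param params base parameter set.
#' @param supply base supply (used, and required, unless `"supply"` is
#'   free).
#' @param weights length-2 weights `c(w1, w2)` for the production and
#'   first-division terms.
#' @param grid_n grid points per dimension for the multistart scan.
#' @return list with `params` (tuned set), `supply`, `objective`, `values`
#'   (achieved production and first-division day) and `trace` (the
#'   objective evaluations).
#' @export
calibrate_average_season <- function(avg, targets, free, lower, upper,
                                     params = cambium_params(), supply = NULL,
                                     weights = c(1, 1), grid_n = 7) {
  if (length(free) == 0L) stop("free parameter set is empty", call. = FALSE)
  if (!all(free %in% c(names(unclass(params)), "supply"))) {
    stop("unknown free parameter(s)", call. = FALSE)
  }
  lower <- lower[free]; upper <- upper[free]
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower >= upper)) {
    stop("each free parameter needs finite bounds with lower < upper",
         call. = FALSE)
  }
  if (is.null(supply) && !"supply" %in% free) {
    stop("supply must be given unless it is a free parameter", call. = FALSE)
  }
  trace <- list()
  measure <- function(theta) {
    p <- params; s <- supply
    for (j in seq_along(free)) {
      if (free[j] == "supply") s <- unname(theta[j])
      else p[[free[j]]] <- unname(theta[j])
    }
    p2 <- tryCatch(validate_params(p), error = function(e) NULL)
    if (is.null(p2)) return(NULL)
    res <- tryCatch(suppressWarnings(simulate_season(avg, p, s)),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    first_div <- if (nrow(res$division_log)) {
      min(res$division_log$division_time)
    } else NA_real_
    list(production = res$production, first_division_day = first_div,
         supply = s, params = p)
  }
  objective <- function(theta) {
    if (any(theta < lower - 1e-12) || any(theta > upper + 1e-12)) {
      return(1e12 + sum(pmax(lower - theta, 0)^2 + pmax(theta - upper, 0)^2))
    }
    mm <- measure(theta)
    if (is.null(mm)) return(1e12)
    obj <- weights[1] * (mm$production - targets$production)^2
    if (!is.null(targets$first_division_day)) {
      fd <- if (is.na(mm$first_division_day)) 1e6 else mm$first_division_day
      obj <- obj + weights[2] * (fd - targets$first_division_day)^2
    }
    trace[[length(trace) + 1L]] <<- c(theta, objective = obj)
    obj
  }

  start <- vapply(free, function(f) {
    if (f == "supply") {
      if (is.null(supply)) mean(c(lower[["supply"]], upper[["supply"]]))
      else supply
    } else params[[f]]
  }, numeric(1))
  start <- pmin(pmax(start, lower), upper)
  f0 <- objective(start)
  best_theta <- start; best_obj <- f0
  if (best_obj > 0) {
    if (length(free) == 1L) {
      gs <- golden_min(objective, lower, upper, tol = 1e-5)
      if (gs$objective < best_obj) {
        best_obj <- gs$objective; best_theta <- gs$theta
      }
    } else {
      grids <- lapply(seq_along(free), function(j)
        seq(lower[j], upper[j], length.out = grid_n))
      cand <- as.matrix(do.call(expand.grid, grids))
      vals <- apply(cand, 1L, objective)
      o <- order(vals)[seq_len(min(3L, nrow(cand)))]
      for (k in o) {
        if (vals[k] < best_obj) { best_obj <- vals[k]; best_theta <- cand[k, ] }
        opt <- stats::optim(cand[k, ], objective, method = "Nelder-Mead",
                            control = list(maxit = 200, reltol = 1e-8))
        if (opt$value < best_obj) {
          best_obj <- opt$value
          best_theta <- pmin(pmax(opt$par, lower), upper)
        }
        if (best_obj == 0) break
      }
    }
  }
  mm <- measure(best_theta)
  list(params = mm$params, supply = mm$supply, objective = best_obj,
       theta = stats::setNames(best_theta, free),
       values = list(production = mm$production,
                     first_division_day = mm$first_division_day),
       trace = trace)
}

# Golden-section minimisation on [lo, hi]; deterministic, derivative-free.
golden_min <- function(f, lo, hi, tol = 1e-5) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while ((b - a) > tol * max(abs(b), 1)) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(x2)
    }
    if (min(f1, f2) == 0) break
  }
  if (f1 <= f2) list(theta = x1, objective = f1)
  else list(theta = x2, objective = f2)
}

#' Study record: years, observations, exclusions and split
#'
#' Bundles a multi-year study: the observed annual cell production, any
#' excluded years (with reasons) and the calibration/verification split.
#'
#' @param years vector of years.
#' @param observed_production observed cells per year (non-negative).
#' @param split list with `calibration` and `verification` year vectors.
#' @param excluded named character vector: names are excluded years, values
#'   the reasons.
#' @return an object of class `study_record`.
#' @export
study_record <- function(years, observed_production, split,
                         excluded = character(0)) {
  stopifnot(length(years) == length(observed_production))
  if (any(observed_production < 0)) {
    stop("observed production must be non-negative", call. = FALSE)
  }
  rec <- structure(
    list(years = as.integer(years),
         observed_production = as.numeric(observed_production),
         split = split, excluded = excluded),
    class = "study_record")
  validate_study_record(rec)
  rec
}

validate_study_record <- function(rec) {
  excl_years <- as.integer(names(rec$excluded))
  both <- c(rec$split$calibration, rec$split$verification)
  if (any(excl_years %in% both)) {
    stop("excluded years must be absent from both split sides", call. = FALSE)
  }
  invisible(rec)
}

#' @export
print.study_record <- function(x, ...) {
  cat(sprintf("Study record: %d years (%d-%d), %d excluded\n",
              length(x$years), min(x$years), max(x$years),
              length(x$excluded)))
  cat(sprintf("  calibration %d years, verification %d years\n",
              length(x$split$calibration), length(x$split$verification)))
  invisible(x)
}

#' Exclude seasons from a study record
#'
#' Removes user-masked years from the study (observations and both split
#' sides), logging the reasons. The discrepancy criterion that motivates an
#' exclusion is the user's: the mask is supplied, not computed.
#'
#' @param record a [study_record()].
#' @param mask named character vector: names are years to exclude, values
#'   are reasons.
#' @return the filtered `study_record` with the mask appended to its
#'   `excluded` log.
#' @export
filter_seasons <- function(record, mask) {
  if (length(mask) == 0L) return(record)
  yrs <- as.integer(names(mask))
  unknown <- setdiff(yrs, record$years)
  if (length(unknown)) {
    stop("mask names year(s) not in the record: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- !(record$years %in% yrs)
  record$years <- record$years[keep]
  record$observed_production <- record$observed_production[keep]
  record$split$calibration <- setdiff(record$split$calibration, yrs)
  record$split$verification <- setdiff(record$split$verification, yrs)
  record$excluded <- c(record$excluded, mask)
  validate_study_record(record)
  record
}

#' Two-step recovery workflow on a multi-year study
#'
#' Runs the season-invariant verification workflow: (1) refit the supply
#' regression against the per-season reference supplies (for synthetic
#' fixtures, the recorded ground truth — the counterpart of manually
#' calculated supplies; optionally inferred from observed production by
#' bisection with `supplies = "infer"`) and compare predicted with reference
#' supplies; (2) simulate production from the predicted supplies and compare
#' with observed production.
#'
#' @param series_set named list of [growth_series()] keyed by year.
#' @param observed data frame with columns `year` and `cells`.
#' @param params a [cambium_params()] object.
#' @param reference_supplies named numeric vector of per-year supplies
#'   (required unless `supplies = "infer"`).
#' @param supplies `"reference"` or `"infer"`.
#' @return list with the refit `model`, per-year data frame `table`
#'   (`year`, `supply_ref`, `supply_pred`, `observed`, `simulated`) and
#'   `R2_supply`, `R2_production` (squared Pearson correlations over all
#'   years).
#' @export
run_study_recovery <- function(series_set, observed,
                               params = cambium_params(),
                               reference_supplies = NULL,
                               supplies = c("reference", "infer")) {
  supplies <- match.arg(supplies)
  years <- sort(vapply(series_set, `[[`, integer(1), "year"))
  series_set <- series_set[order(vapply(series_set, `[[`, integer(1),
                                        "year"))]
  obs <- observed$cells[match(years, observed$year)]
  if (any(is.na(obs))) stop("observed production missing for some years",
                            call. = FALSE)
  ref <- if (supplies == "reference") {
    if (is.null(reference_supplies)) {
      stop("reference_supplies required", call. = FALSE)
    }
    as.numeric(reference_supplies[as.character(years)])
  } else {
    vapply(seq_along(years), function(k) {
      infer_supply_for_production(series_set[[k]], params, obs[k])$supply
    }, numeric(1))
  }
  stats_list <- lapply(series_set, season_stats, params = params)
  skew <- vapply(stats_list, `[[`, numeric(1), "skew")
  skew_prev <- c(params$skew_default, skew[-length(skew)])
  train <- do.call(rbind, lapply(seq_along(years), function(k) {
    st <- stats_list[[k]]
    data.frame(sd = st[["sd"]], median = st[["median"]], mad = st[["mad"]],
               min = st[["min"]], max = st[["max"]],
               skew_prev = skew_prev[k], supply = ref[k])
  }))
  model <- fit_supply_regression(train)
  pred <- predict(model, train)
  sim <- vapply(seq_along(years), function(k) {
    suppressWarnings(
      simulate_season(series_set[[k]], params, pred[k])$production)
  }, numeric(1))
  list(model = model,
       table = data.frame(year = years, supply_ref = ref,
                          supply_pred = pred, observed = obs,
                          simulated = sim),
       R2_supply = stats::cor(ref, pred)^2,
       R2_production = stats::cor(obs, sim)^2)
}
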