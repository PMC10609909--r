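#' Simulate one growing season of cambial activity
#'
#' Runs the radial-file simulation for one season. The season starts with a
#' single initial cell of diameter `D_init` holding the whole inhibitor
#' `supply`, carried to its first division at the constant rate
#' `(D_div - D_init) / d_init`. Thereafter every cell in the file advances
#' concurrently in daily steps with piecewise-analytic within-day event
#' resolution: G1 cells grow at the Gompertz rate of their current inhibitor
#' concentration (recomputed at day and phase boundaries), S/G2/M cells at
#' `V0`. A cell reaching the division diameter divides if its concentration
#' is at least `C_min` — the division is stress-flagged when the daily
#' growth rate declined strictly for three or more days beforehand, and the
#' inhibitor is split `alpha` / `1 - alpha` between the proximal and distal
#' daughters — and is otherwise exported to the enlargement zone
#' (`production` increments and its inhibitor leaves the row). Daughters
#' below `C_min` at birth are exported immediately. The initial cell
#' (position 0) never exports; once below threshold it halts and the row
#' can only drain.
#'
#' The season ends when simulated time reaches the environmental season
#' length (`termination_reason = "env_season_end"`) or when no cell in the
#' row has concentration at least `C_min`, i.e. the supply is effectively
#' consumed (`"supply_consumed"`; checked at day boundaries). A supply not
#' exceeding `C_min * D_init` cannot support any division and returns
#' production 0 immediately.
#'
#' @param series a [growth_series()] for the season.
#' @param params a [cambium_params()] object.
#' @param supply inhibitor supply of the initial cell (relative units).
#' @return an object of class `season_result`: a list with `year`,
#'   `supply_used`, `production`, `simulated_season_length`,
#'   `env_season_length`, `termination_reason`, `division_log` (one row per
#'   division, times in days from season start rounded to 0.001),
#'   `exports` (one row per exported cell), `kinetics` (per-day means, see
#'   [extract_kinetics()]), `cells_end` (cells left in the row) and
#'   `n_divisions`.
#' @examples
#' gs <- gen_growth_series(fixture_config(n_years = 1, seed = 1))[[1]]
#' res <- simulate_season(gs, cambium_params(), supply = 2.5)
#' res$production
#' @export
simulate_season <- function(series, params = cambium_params(), supply) {
  validate_params(params)
  validate_growth_series(series)
  if (!is.numeric(supply) || length(supply) != 1L || !is.finite(supply)) {
    stop("supply must be a single finite number", call. = FALSE)
  }
  n_days <- length(series$rates)
  empty_log <- division_log_frame()
  empty_exp <- data.frame(time = numeric(0), cell_id = character(0),
                          inhibitor = numeric(0), at_birth = logical(0),
                          stringsAsFactors = FALSE)
  if (supply <= 0) {
    warning("non-positive inhibitor supply (", signif(supply, 4),
            "): no growth possible", call. = FALSE)
  }
  if (supply <= params$C_min * params$D_init) {
    return(new_season_result(series, params, supply, production = 0L,
                             sim_len = 0, reason = "supply_consumed",
                             log = empty_log, exports = empty_exp,
                             kinetics = kinetics_frame(), cells = list(),
                             n_div = 0L))
  }

  r_init <- initial_linear_rate(params)
  init <- cambial_cell("0", params$D_init, supply, position = 0L,
                       params = params, born_at = 0, regime = "constant")
  init$g1_rate_birth <- r_init

  # cells and a parallel id vector live in an environment; positions are
  # implicit (index - 1, the initial cell first) so structural changes need
  # no per-cell renumbering
  st <- new.env(parent = emptyenv())
  st$cells <- list(init)
  st$ids <- "0"
  st$production <- 0L
  st$exported_inh <- 0
  st$log <- list()
  st$exports <- list()
  st$last_event <- 0
  st$n_div <- 0L
  kin_gr <- kin_g1 <- kin_conc <- kin_row <- kin_exp <- rep(NA_real_, n_days)
  kin_n <- kin_prod <- rep(NA_integer_, n_days)
  n_recorded <- 0L
  div_cap <- 100000L

  find_cell <- function(id) match(id, st$ids)
  regime_rate <- function(cell, gr_today) {
    if (cell$regime == "constant") r_init
    else if (cell$phase == "G1") {
      g1_rate(concentration(cell$inhibitor, cell$diameter), cell$stressed,
              gr_today, params)
    } else params$V0
  }
  export_cell <- function(idx, at, at_birth = FALSE) {
    cell <- st$cells[[idx]]
    st$production <- st$production + 1L
    st$exported_inh <- st$exported_inh + cell$inhibitor
    st$exports[[length(st$exports) + 1L]] <-
      list(time = at, cell_id = cell$id, inhibitor = cell$inhibitor,
           at_birth = at_birth)
    st$cells[[idx]] <- NULL
    st$ids <- st$ids[-idx]
    st$last_event <- max(st$last_event, at)
  }

  reason <- "env_season_end"
  for (day in seq_len(n_days)) {
    t0 <- day - 1
    gr_today <- series$rates[day]
    concs <- vapply(st$cells, function(cl)
      concentration(cl$inhibitor, cl$diameter), numeric(1))
    if (!any(concs >= params$C_min)) {
      reason <- "supply_consumed"
      break
    }
    # daily kinetics snapshot at the start of the day
    in_g1 <- vapply(st$cells, function(cl)
      !cl$halted && cl$phase == "G1", logical(1))
    g1_rates <- if (any(in_g1)) {
      vapply(st$cells[in_g1], regime_rate, numeric(1), gr_today = gr_today)
    } else numeric(0)
    n_recorded <- day
    kin_gr[day] <- gr_today
    kin_n[day] <- length(st$cells)
    kin_g1[day] <- if (length(g1_rates)) mean(g1_rates) else NA_real_
    kin_conc[day] <- mean(concs)
    kin_row[day] <- sum(vapply(st$cells, `[[`, numeric(1), "inhibitor"))
    kin_exp[day] <- st$exported_inh
    kin_prod[day] <- st$production

    # advance every cell (and daughters born today) to the end of the day
    queue_id <- vapply(st$cells, `[[`, character(1), "id")
    queue_t <- rep(t0, length(queue_id))
    while (length(queue_id)) {
      id <- queue_id[1L]; t_now <- queue_t[1L]
      queue_id <- queue_id[-1L]; queue_t <- queue_t[-1L]
      idx <- find_cell(id)
      if (is.na(idx)) next
      cell <- st$cells[[idx]]
      if (cell$halted) next
      budget <- day - t_now
      if (budget <= 1e-12) next
      before_na <- is.na(cell$phase_entry)
      res <- advance_cell_core(cell, regime_rate(cell, gr_today), budget,
                               params)
      cell <- res$cell
      newly <- before_na & !is.na(cell$phase_entry)
      cell$phase_entry[newly] <- cell$phase_entry[newly] + t_now
      n_ev <- length(res$ev_t)
      ready <- n_ev > 0L && res$ev_ty[n_ev] == "ready_to_divide"
      if (!ready) {
        st$cells[[idx]] <- cell
        next
      }
      tr <- t_now + res$ev_t[n_ev]
      if (concentration(cell$inhibitor, cell$diameter) < params$C_min) {
        if (idx == 1L) {            # the initial cell never exports
          cell$halted <- TRUE
          st$cells[[idx]] <- cell
        } else {
          export_cell(idx, tr)
        }
        next
      }
      # division
      di <- max(1L, min(n_days, as.integer(ceiling(tr - 1e-9))))
      stress <- detect_stress_window(series, di)
      st$n_div <- st$n_div + 1L
      if (st$n_div > div_cap) {
        stop("division cap exceeded; simulation does not terminate",
             call. = FALSE)
      }
      st$last_event <- max(st$last_event, tr)
      cell$position <- idx - 1L
      st$log[[st$n_div]] <- division_record(cell, tr, stress)
      dts <- divide_cell(cell, params$alpha, stress, at = tr, params = params)
      st$cells[[idx]] <- dts$proximal
      st$cells <- append(st$cells, list(dts$distal), after = idx)
      st$ids[idx] <- dts$proximal$id
      st$ids <- append(st$ids, dts$distal$id, after = idx)
      # birth-time exit checks (the position-0 cell never exports)
      for (dname in c("distal", "proximal")) {
        j <- find_cell(dts[[dname]]$id)
        dcell <- st$cells[[j]]
        dcell$g1_rate_birth <- regime_rate(dcell, gr_today)
        st$cells[[j]] <- dcell
        if (should_exit(dcell, params) && j > 1L) {
          export_cell(j, tr, at_birth = TRUE)
        } else if (day - tr > 1e-12) {
          queue_id <- c(queue_id, dcell$id)
          queue_t <- c(queue_t, tr)
        }
      }
    }
  }

  for (k in seq_along(st$cells)) st$cells[[k]]$position <- k - 1L
  sim_len <- if (reason == "env_season_end") n_days else st$last_event
  log <- if (st$n_div) {
    do.call(rbind, lapply(st$log, as.data.frame, stringsAsFactors = FALSE))
  } else empty_log
  exports <- if (length(st$exports)) {
    do.call(rbind, lapply(st$exports, as.data.frame,
                          stringsAsFactors = FALSE))
  } else empty_exp
  kin <- if (n_recorded > 0L) {
    keep <- seq_len(n_recorded)
    data.frame(day = keep, gr = kin_gr[keep], n_cells = kin_n[keep],
               g1_rate_mean = kin_g1[keep],
               concentration_mean = kin_conc[keep],
               inhibitor_in_row = kin_row[keep],
               inhibitor_exported = kin_exp[keep],
               production = kin_prod[keep])
  } else kinetics_frame()
  new_season_result(series, params, supply, st$production, sim_len, reason,
                    log, exports, kin, st$cells, st$n_div)
}

division_log_frame <- function() {
  data.frame(appearance_date = numeric(0), g1_time = numeric(0),
             s_time = numeric(0), g2_time = numeric(0), m_time = numeric(0),
             cycle_time = numeric(0), inhibitor_received = numeric(0),
             g1_rate_at_birth = numeric(0), concentration_at_M = numeric(0),
             cell_id = character(0), mother_id = character(0),
             division_time = numeric(0), stress = logical(0),
             stringsAsFactors = FALSE)
}

kinetics_frame <- function() {
  data.frame(day = integer(0), gr = numeric(0), n_cells = integer(0),
              g1_rate_mean = numeric(0), concentration_mean = numeric(0),
              inhibitor_in_row = numeric(0), inhibitor_exported = numeric(0),
              production = integer(0))
}

# One division-log row; times reported to 0.001 d.
division_record <- function(cell, t_div, stress) {
  en <- cell$phase_entry
  g1 <- if (!is.na(en[["S"]])) en[["S"]] - cell$born_at else t_div - cell$born_at
  s <- if (!is.na(en[["G2"]]) && !is.na(en[["S"]])) en[["G2"]] - en[["S"]] else 0
  g2 <- if (!is.na(en[["M"]]) && !is.na(en[["G2"]])) en[["M"]] - en[["G2"]] else 0
  m <- if (!is.na(en[["M"]])) t_div - en[["M"]] else 0
  list(appearance_date = round(cell$born_at, 3),
       g1_time = round(g1, 3), s_time = round(s, 3), g2_time = round(g2, 3),
       m_time = round(m, 3), cycle_time = round(t_div - cell$born_at, 3),
       inhibitor_received = cell$inhibitor,
       g1_rate_at_birth = cell$g1_rate_birth,
       concentration_at_M = concentration(cell$inhibitor, cell$diameter),
       cell_id = cell$id, mother_id = cell$mother_id,
       division_time = round(t_div, 3), stress = stress)
}

new_season_result <- function(series, params, supply, production, sim_len,
                              reason, log, exports, kinetics, cells, n_div) {
  structure(
    list(year = series$year, supply_used = as.numeric(supply),
         production = as.integer(production),
         simulated_season_length = sim_len,
         env_season_length = season_length(series),
         termination_reason = reason, division_log = log, exports = exports,
         kinetics = kinetics, cells_end = cells, n_divisions = n_div,
         params = params),
    class = "season_result")
}

#' @export
print.season_result <- function(x, ...) {
  cat(sprintf("Season %s: supply %.4f -> production %d cells (%d divisions)\n",
              ifelse(is.na(x$year), "(synthetic)", x$year), x$supply_used,
              x$production, x$n_divisions))
  cat(sprintf("  simulated length %.3f d of %d d environmental season (%s)\n",
              x$simulated_season_length, x$env_season_length,
              x$termination_reason))
  invisible(x)
}

#' @export
summary.season_result <- function(object, ...) {
  print(object)
  if (nrow(object$division_log)) {
    cat("Division log (first rows):\n")
    print(utils::head(object$division_log[, c("appearance_date", "cycle_time",
                                              "inhibitor_received",
                                              "concentration_at_M",
                                              "cell_id")], 5))
  }
  invisible(object)
}

#' @export
plot.season_result <- function(x, ...) {
  kin <- x$kinetics
  if (nrow(kin) == 0L) {
    warning("no kinetics to plot", call. = FALSE)
    return(invisible(x))
  }
  graphics::matplot(kin$day, cbind(kin$gr, kin$g1_rate_mean,
                                   kin$concentration_mean),
                    type = "l", lty = 1, lwd = 2,
                    col = c("#7fb3d5", "#1f618d", "#148f77"),
                    xlab = "day of season",
                    ylab = "rate / concentration (relative units)", ...)
  graphics::legend("topright", bty = "n",
                   legend = c("external growth rate", "mean G1 rate",
                              "mean inhibitor concentration"),
                   col = c("#7fb3d5", "#1f618d", "#148f77"), lwd = 2)
  invisible(x)
}

#' Per-day cambial kinetics of a simulated season
#'
#' Extracts the daily kinetics: the mean G1 growth rate over cells currently
#' in G1 (`NA` on days with no G1 cell), the mean inhibitor concentration
#' over the row, and the external daily growth rate.
#'
#' @param result a [simulate_season()] result with at least one simulated
#'   day.
#' @return data frame with columns `day`, `g1_rate_mean`,
#'   `concentration_mean`, `gr`.
#' @export
extract_kinetics <- function(result) {
  kin <- result$kinetics
  if (nrow(kin) == 0L) stop("season has no simulated days", call. = FALSE)
  kin[, c("day", "g1_rate_mean", "concentration_mean", "gr")]
}

#' Correlations among spline-smoothed kinetics
#'
#' Smooths each kinetics series (mean G1 rate, mean inhibitor concentration,
#' external growth rate) with a cubic smoothing spline and reports the
#' pairwise Pearson correlations and their squares, mirroring how simulated
#' cambial kinetics are compared with the external forcing.
#'
#' @param kinetics data frame from [extract_kinetics()] (columns `day`,
#'   `g1_rate_mean`, `concentration_mean`, `gr`).
#' @param spar smoothing parameter passed to [stats::smooth.spline()]
#'   (`NULL` for its internal cross-validated choice).
#' @return data frame with one row per pair (`g1~gr`, `conc~gr`,
#'   `g1~conc`) and columns `pair`, `r`, `r2`.
#' @export
kinetics_correlations <- function(kinetics, spar = 0.5) {
  ok <- stats::complete.cases(kinetics[, c("day", "g1_rate_mean",
                                           "concentration_mean", "gr")])
  kin <- kinetics[ok, , drop = FALSE]
  if (nrow(kin) < 10L) {
    stop("need at least 10 complete kinetics days, got ", nrow(kin),
         call. = FALSE)
  }
  sm <- function(y) {
    if (stats::sd(y) == 0) return(y)
    stats::fitted(stats::smooth.spline(kin$day, y, spar = spar))
  }
  g1 <- sm(kin$g1_rate_mean); cc <- sm(kin$concentration_mean)
  gr <- sm(kin$gr)
  pr <- function(a, b) stats::cor(a, b)
  r <- c(pr(g1, gr), pr(cc, gr), pr(g1, cc))
  data.frame(pair = c("g1~gr", "conc~gr", "g1~conc"), r = r, r2 = r^2,
             stringsAsFactors = FALSE)
}
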