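# Naive fixed-step reference simulator. Same model rules as the package's
# event-driven engine (daily G1-rate refresh, stress flags, birth/division
# exit checks, day-boundary termination scan) but integrated by brute-force
# Euler stepping at a small dt, with threshold crossings detected on the
# grid. Kept deliberately independent of the engine's event algebra so the
# two can cross-check each other.
oracle_simulate <- function(series, params, supply, dt = 5e-4) {
  n_days <- length(series$rates)
  g1r <- function(C, str) {
    arg <- ifelse(str,
                  if (params$stress_mode == "literal") {
                    params$c_g1 * params$S_stress * C
                  } else params$c_g1 * C / params$S_stress,
                  params$c_g1 * C)
    exp(-exp(-arg))
  }
  band_of <- function(d) {
    if (d < params$D_S) 1L else if (d < params$D_G2) 2L
    else if (d < params$D_M) 3L else 4L
  }
  stress_at <- function(t) {
    d <- max(1L, min(n_days, as.integer(ceiling(t - 1e-9))))
    if (d < 4L) return(FALSE)
    all(diff(series$rates[(d - 3L):d]) < 0)
  }
  out <- list(production = 0L, divisions = numeric(0), exports = numeric(0),
              reason = "env_season_end")
  if (supply <= params$C_min * params$D_init) {
    out$reason <- "supply_consumed"
    return(out)
  }
  thr <- c(params$D_S, params$D_G2, params$D_M, params$D_div)
  diam <- params$D_init; inh <- supply; band <- 1L
  const <- TRUE; stressed <- FALSE; halted <- FALSE
  rate <- (params$D_div - params$D_init) / params$d_init
  steps_per_day <- as.integer(round(1 / dt))
  n_guard <- 0L
  for (day in seq_len(n_days)) {
    if (!any(inh / diam >= params$C_min)) {
      out$reason <- "supply_consumed"
      break
    }
    gr <- series$rates[day]
    idx_g1 <- which(!const & band == 1L & !halted)
    if (length(idx_g1)) {
      rate[idx_g1] <- g1r(inh[idx_g1] / diam[idx_g1], stressed[idx_g1])
    }
    for (s in seq_len(steps_per_day)) {
      act <- !halted
      diam[act] <- diam[act] + rate[act] * dt
      if (!any(diam[act] >= thr[band[act]] - 1e-12)) next
      t_now <- (day - 1) + s * dt
      repeat {
        hit <- which(!halted & diam >= thr[band] - 1e-12)
        if (!length(hit)) break
        i <- hit[1L]
        if (band[i] < 4L) {
          band[i] <- band[i] + 1L
          if (!const[i]) rate[i] <- params$V0
          next
        }
        diam[i] <- params$D_div
        if (inh[i] / diam[i] < params$C_min) {
          if (i == 1L) {
            halted[i] <- TRUE
          } else {
            out$production <- out$production + 1L
            out$exports <- c(out$exports, t_now)
            diam <- diam[-i]; inh <- inh[-i]; band <- band[-i]
            const <- const[-i]; stressed <- stressed[-i]
            halted <- halted[-i]; rate <- rate[-i]
          }
          next
        }
        n_guard <- n_guard + 1L
        if (n_guard > 100000L) stop("oracle division cap exceeded")
        str <- stress_at(t_now)
        out$divisions <- c(out$divisions, t_now)
        half <- diam[i] / 2
        pi_ <- inh[i] * params$alpha; di_ <- inh[i] * (1 - params$alpha)
        ins <- function(v, at, vals) append(v[-at], vals, after = at - 1L)
        diam <- ins(diam, i, c(half, half))
        inh <- ins(inh, i, c(pi_, di_))
        band <- ins(band, i, c(band_of(half), band_of(half)))
        const <- ins(const, i, c(FALSE, FALSE))
        stressed <- ins(stressed, i, c(str, str))
        halted <- ins(halted, i, c(FALSE, FALSE))
        rr <- g1r(c(pi_, di_) / half, c(str, str))
        rate <- ins(rate, i, rr)
        for (j in c(i + 1L, i)) {    # distal first, then proximal
          if (j > 1L && inh[j] / diam[j] < params$C_min) {
            out$production <- out$production + 1L
            out$exports <- c(out$exports, t_now)
            diam <- diam[-j]; inh <- inh[-j]; band <- band[-j]
            const <- const[-j]; stressed <- stressed[-j]
            halted <- halted[-j]; rate <- rate[-j]
          }
        }
      }
    }
    if (out$reason == "supply_consumed") break
  }
  out
}
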