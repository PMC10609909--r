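p <- cambium_params()

test_that("zero or sub-threshold supply yields an immediate empty season", {
  gs <- make_bell_series()
  expect_warning(res0 <- simulate_season(gs, p, 0), "non-positive")
  expect_equal(res0$production, 0L)
  expect_equal(res0$termination_reason, "supply_consumed")
  expect_equal(nrow(res0$division_log), 0L)

  res_tiny <- simulate_season(gs, p, p$C_min * p$D_init)  # boundary: no growth
  expect_equal(res_tiny$production, 0L)
})

test_that("the same inputs give byte-identical division logs", {
  gs <- make_random_series(120, seed = 21)
  a <- simulate_season(gs, p, 2.2)
  b <- simulate_season(gs, p, 2.2)
  expect_identical(a$division_log, b$division_log)
  expect_identical(a$kinetics, b$kinetics)
  expect_identical(a$production, b$production)
})

test_that("the row bookkeeping balances divisions, exports and survivors", {
  gs <- make_bell_series()
  res <- simulate_season(gs, p, 2.5)
  expect_gt(res$production, 0)
  expect_equal(length(res$cells_end) + res$production, 1 + res$n_divisions)
  expect_lte(res$simulated_season_length, res$env_season_length)
  expect_true(all(res$division_log$cycle_time >= 0))
  # cycle time equals the phase-time sum within rounding slack
  sums <- with(res$division_log, g1_time + s_time + g2_time + m_time)
  expect_true(all(abs(sums - res$division_log$cycle_time) <= 0.002 + 1e-9))
})

test_that("inhibitor ledger balances at every daily checkpoint", {
  gs <- make_bell_series()
  for (supply in c(0.8, 2.5, 4)) {
    res <- simulate_season(gs, p, supply)
    drift <- res$kinetics$inhibitor_in_row + res$kinetics$inhibitor_exported -
      supply
    expect_lt(max(abs(drift)), 1e-9)
  }
})

test_that("production is non-decreasing in supply", {
  gs <- make_bell_series()
  supplies <- seq(0.2, 5, length.out = 20)
  prods <- vapply(supplies, function(s)
    suppressWarnings(simulate_season(gs, p, s)$production), integer(1))
  expect_true(all(diff(prods) >= 0))
})

test_that("event-driven engine matches the fixed-step oracle", {
  gs <- growth_series(NA, 127, 127 + 157, rep(1, 158))  # constant forcing
  res <- simulate_season(gs, p, 2.0)
  orc <- oracle_simulate(gs, p, 2.0, dt = 5e-4)
  expect_lte(abs(res$production - orc$production), 1)
  if (res$n_divisions == length(orc$divisions)) {
    expect_lt(max(abs(sort(res$division_log$division_time) -
                        sort(orc$divisions))), 0.01)
  }
})

test_that("the simulation halts for extreme but legal inputs", {
  gs <- make_bell_series(60)
  res <- simulate_season(gs, p, 500)   # huge supply: season-length limited
  expect_true(res$termination_reason %in%
                c("env_season_end", "supply_consumed"))
  expect_true(is.finite(res$production))
  p2 <- update_params(p, alpha = 0.99)
  res2 <- simulate_season(gs, p2, 3)
  expect_true(is.finite(res2$production))
})

test_that("production magnitude is plausible for the default parameters", {
  gs <- make_bell_series()           # 159-day bell season, DOY 127-285
  res <- simulate_season(gs, p, 2.5)
  expect_gte(res$production, 10)
  expect_lte(res$production, 40)
})

test_that("kinetics carry missing markers, not zeros, when G1 is empty", {
  gs <- make_bell_series()
  res <- simulate_season(gs, p, 2.5)
  kin <- extract_kinetics(res)
  expect_named(kin, c("day", "g1_rate_mean", "concentration_mean", "gr"))
  # day 8 follows the first division at t = 7.5: daughters are in G1
  expect_false(is.na(kin$g1_rate_mean[9]))
  expect_true(all(is.na(kin$g1_rate_mean) | kin$g1_rate_mean > 0))
  expect_true(all(kin$concentration_mean > 0))
})

test_that("a single-cell season's kinetics equal the cell's own trajectory", {
  # supply just above threshold: initial cell never gains a partner
  gs <- make_bell_series(30)
  supply <- 0.2
  res <- simulate_season(gs, p, supply)
  expect_equal(res$production, 0L)
  kin <- extract_kinetics(res)
  expect_equal(kin$gr, gs$rates[seq_len(nrow(kin))])
  # single linear-regime cell: concentration = supply / diameter at day start
  r0 <- initial_linear_rate(p)
  days <- kin$day - 1
  expected_conc <- supply / pmin(p$D_init + r0 * days, p$D_div)
  expect_equal(kin$concentration_mean, expected_conc, tolerance = 1e-9)
})

test_that("toy kinetics means are the hand-computed per-day averages", {
  gs <- make_bell_series()
  res <- simulate_season(gs, p, 2.5)
  k <- res$kinetics
  # reconstruct day-1 numbers by hand: one initial cell, conc supply/D_init
  expect_equal(k$concentration_mean[1], 2.5 / p$D_init)
  expect_equal(k$g1_rate_mean[1], initial_linear_rate(p))
  expect_equal(k$n_cells[1], 1L)
})

test_that("kinetics correlations behave on degenerate and lagged series", {
  day <- 1:80
  s1 <- sin(2 * pi * day / 40)
  kin_same <- data.frame(day = day, g1_rate_mean = s1,
                         concentration_mean = s1, gr = s1)
  rs <- kinetics_correlations(kin_same, spar = 0.3)
  expect_equal(rs$r, rep(1, 3), tolerance = 1e-6)

  kin_neg <- data.frame(day = day, g1_rate_mean = s1,
                        concentration_mean = -s1, gr = s1)
  rn <- kinetics_correlations(kin_neg, spar = 0.3)
  expect_equal(rn$r[rn$pair == "g1~conc"], -1, tolerance = 1e-6)

  lag <- 5                              # phase lag over a 40-day period
  s2 <- sin(2 * pi * (day + lag) / 40)
  kin_lag <- data.frame(day = day, g1_rate_mean = s1,
                        concentration_mean = s2, gr = s1)
  rl <- kinetics_correlations(kin_lag, spar = 0.3)
  expect_equal(rl$r[rl$pair == "g1~conc"], cos(2 * pi * lag / 40),
               tolerance = 0.02)

  expect_error(kinetics_correlations(kin_same[1:5, ]), "at least 10")
})

test_that("stressed daughters carry the stress flag into the log", {
  # force a deep decline right before mid-season divisions
  n <- 100
  r <- rep(0.8, n)
  r[40:48] <- seq(0.8, 0.2, length.out = 9)
  gs <- growth_series(NA, 127, 127 + n - 1, r)
  res <- simulate_season(gs, p, 2.5)
  in_window <- res$division_log$division_time > 43 &
    res$division_log$division_time <= 48
  if (any(in_window)) expect_true(all(res$division_log$stress[in_window]))
  expect_true(any(res$division_log$stress))
})
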