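p <- cambium_params()

test_that("supply inversion round-trips through the simulator", {
  set.seed(31)
  for (k in 1:6) {
    gs <- make_random_series(sample(60:110, 1), seed = 100 + k)
    s_true <- runif(1, 1, 3.5)
    target <- suppressWarnings(simulate_season(gs, p, s_true)$production)
    if (target == 0) next
    inv <- infer_supply_for_production(gs, p, target)
    expect_true(inv$attained)
    expect_equal(inv$production, target)
    expect_equal(
      suppressWarnings(simulate_season(gs, p, inv$supply)$production), target)
  }
})

test_that("supply inversion handles degenerate targets", {
  gs <- make_bell_series(60)
  expect_equal(infer_supply_for_production(gs, p, 0)$supply, 0)
  big <- infer_supply_for_production(gs, p, 1e6)
  expect_false(big$attained)
  expect_lt(big$production, 1e6)
  expect_error(infer_supply_for_production(gs, p, Inf), "finite")
})

test_that("multi-year reconstruction is reproducible and warns as contracted", {
  series <- gen_growth_series(fixture_config(n_years = 3, seed = 5))
  w <- capture_warnings(tab <- run_multi_year(series, p))
  expect_match(w, "previous season absent", all = FALSE)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$year, 1963:1965)
  tab2 <- suppressWarnings(run_multi_year(series, p))
  expect_identical(tab$production, tab2$production)

  neg_model <- supply_model(intercept = -5, beta_sd = 0, beta_median = 0,
                            beta_mad = 0, beta_min = 0, beta_max = 0,
                            beta_skew_prev = 0)
  wn <- capture_warnings(nt <- run_multi_year(series, p, neg_model))
  expect_match(wn, "non-positive predicted supply", all = FALSE)
  expect_true(all(nt$production == 0))
  expect_true(all(nt$supply_nonpositive))
})

test_that("reconstruction reproduces fixture truth when noise is off", {
  fx <- gen_study_fixture(fixture_config(n_years = 6, seed = 9))
  tab <- suppressWarnings(
    run_multi_year(fx$series, fx$truth$params, fx$truth$regression))
  expect_equal(tab$production, fx$observed$cells)
  expect_equal(unname(tab$supply), unname(fx$truth$supply[as.character(tab$year)]),
               tolerance = 1e-10)
})

test_that("split goodness is squared Pearson correlation per period", {
  years <- 1963:1974
  split <- list(calibration = 1969:1974, verification = 1963:1968)
  obs <- c(10, 14, 12, 18, 16, 20, 11, 13, 17, 15, 19, 12)
  expect_equal(split_goodness(obs, obs, years, split)$R2_calibration, 1)
  expect_equal(split_goodness(obs, obs, years, split)$R2_verification, 1)

  sim <- 2 * obs + 3           # affine map: r = 1 either side
  gf <- split_goodness(obs, sim, years, split)
  expect_equal(gf$r_overall, 1)

  set.seed(8)
  perm <- sample(obs)          # fixed-seed permutation: near-zero association
  gfp <- split_goodness(obs, perm, years, split)
  expect_lt(gfp$R2_calibration, 0.5)

  o6 <- c(1, 3, 2, 5, 4, 6); s6 <- c(2, 2, 3, 6, 4, 5)
  hand_r <- sum((o6 - mean(o6)) * (s6 - mean(s6))) /
    sqrt(sum((o6 - mean(o6))^2) * sum((s6 - mean(s6))^2))
  gfh <- split_goodness(o6, s6, 1:6,
                        list(calibration = 1:3, verification = 4:6))
  expect_equal(gfh$r_overall, hand_r, tolerance = 1e-12)
  expect_error(
    split_goodness(rep(1, 6), s6, 1:6,
                   list(calibration = 1:3, verification = 4:6)),
    "calibration")
})

test_that("average-season tuning returns immediately when targets are met", {
  avg <- build_average_season(gen_growth_series(fixture_config(n_years = 4,
                                                               seed = 2)))
  base <- simulate_season(avg, p, 2.5)
  first_div <- min(base$division_log$division_time)
  cal <- calibrate_average_season(
    avg, targets = list(production = base$production,
                        first_division_day = first_div),
    free = "alpha", lower = c(alpha = 0.6), upper = c(alpha = 0.95),
    params = p, supply = 2.5)
  expect_equal(cal$objective, 0)
  expect_equal(cal$params$alpha, p$alpha)
})

test_that("tuning a free supply agrees with bisection inversion", {
  avg <- build_average_season(gen_growth_series(fixture_config(n_years = 4,
                                                               seed = 2)))
  target <- simulate_season(avg, p, 2.8)$production
  cal <- calibrate_average_season(
    avg, targets = list(production = target), free = "supply",
    lower = c(supply = 0.5), upper = c(supply = 6), params = p,
    weights = c(1, 0))
  expect_equal(cal$objective, 0)
  expect_equal(cal$values$production, target)
  inv <- infer_supply_for_production(avg, p, target)
  expect_equal(
    suppressWarnings(simulate_season(avg, p, cal$supply)$production),
    inv$production)
})

test_that("a known inhibitor-partition coefficient is recovered", {
  avg <- build_average_season(gen_growth_series(fixture_config(n_years = 4,
                                                               seed = 2)))
  truth <- update_params(p, alpha = 0.75)
  res <- simulate_season(avg, truth, 2.5)
  cal <- calibrate_average_season(
    avg, targets = list(production = res$production,
                        first_division_day =
                          min(res$division_log$division_time)),
    free = "alpha", lower = c(alpha = 0.55), upper = c(alpha = 0.95),
    params = p, supply = 2.5)
  expect_equal(cal$objective, 0)
  expect_lt(abs(cal$params$alpha - 0.75), 0.05)
})

test_that("season filtering removes masked years with logged reasons", {
  years <- 1963:2011
  rec <- study_record(years, observed_production = rep(20, length(years)),
                      split = list(calibration = 1989:2011,
                                   verification = 1963:1987))
  expect_identical(filter_seasons(rec, character(0)), rec)

  one <- filter_seasons(rec, c("1978" = "missing data"))
  expect_false(1978 %in% one$years)
  expect_false(1978 %in% one$split$verification)

  mask <- c("1978" = "cell production data not prepared",
            "2003" = "cell production data not prepared",
            "1977" = "growth discrepancy", "1988" = "growth discrepancy",
            "2001" = "growth discrepancy", "2008" = "growth discrepancy")
  filt <- filter_seasons(rec, mask)
  expect_equal(length(filt$years), 43L)       # 49 years minus 6 removals
  expect_equal(length(filt$excluded), 6L)
  expect_error(filter_seasons(rec, c("1900" = "x")), "1900")
})

test_that("end-to-end recovery is exact when the fixture is noise-free", {
  fx <- gen_study_fixture(fixture_config(n_years = 10, seed = 4))
  rec <- run_study_recovery(fx$series, fx$observed, fx$truth$params,
                            fx$truth$supply)
  expect_equal(rec$R2_supply, 1, tolerance = 1e-8)
  expect_equal(rec$R2_production, 1, tolerance = 1e-8)
  expect_equal(coef(rec$model), coef(fx$truth$regression), tolerance = 1e-6)
})

test_that("recovery stays strong under the stated supply noise", {
  fx <- gen_study_fixture(fixture_config(n_years = 40, seed = 1,
                                         supply_noise_frac = 0.15))
  rec <- run_study_recovery(fx$series, fx$observed, fx$truth$params,
                            fx$truth$supply)
  expect_gte(cor(fx$truth$supply_clean, rec$table$supply_pred)^2, 0.8)
  expect_gte(cor(fx$truth$production_clean, rec$table$simulated)^2, 0.8)
})

test_that("bisection-inferred supplies support the workflow too", {
  fx <- gen_study_fixture(fixture_config(n_years = 8, seed = 6))
  rec <- run_study_recovery(fx$series, fx$observed, fx$truth$params,
                            supplies = "infer")
  # inferred supplies sit at the edge of a production-staircase tread, so
  # agreement is tight but not exact
  expect_gte(rec$R2_supply, 0.9)
  expect_gte(cor(rec$table$simulated, fx$observed$cells)^2, 0.8)
})
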