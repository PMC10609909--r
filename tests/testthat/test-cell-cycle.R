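p <- cambium_params()

test_that("concentration is amount over diameter and rejects bad sizes", {
  expect_equal(concentration(0, 5), 0)
  expect_equal(concentration(0.8286, 4.75), 0.8286 / 4.75)
  expect_equal(concentration(3 * 0.7, 6.1), 3 * concentration(0.7, 6.1))
  expect_error(concentration(1, 0), "positive")
})

test_that("G1 Gompertz rate has the right anchors, limit and monotonicity", {
  expect_equal(g1_rate(0, params = p), exp(-1))
  expect_equal(g1_rate(1, params = p), exp(-exp(-0.071)), tolerance = 1e-12)
  expect_equal(g1_rate(1, params = p), 0.3940, tolerance = 1e-4)
  expect_equal(g1_rate(1e9, params = p), 1, tolerance = 1e-6)
  C <- seq(0, 50, length.out = 200)
  v <- vapply(C, g1_rate, numeric(1), params = p)
  expect_true(all(diff(v) > 0))
  expect_true(all(v > 0 & v <= 1))
})

test_that("stress direction follows the configured mode", {
  C <- c(0.05, 0.2, 1)
  lit <- cambium_params(stress_mode = "literal")
  rec <- cambium_params(stress_mode = "reciprocal")
  for (cc in C) {
    expect_gte(g1_rate(cc, stressed = TRUE, params = lit),
               g1_rate(cc, stressed = FALSE, params = lit))
    expect_lte(g1_rate(cc, stressed = TRUE, params = rec),
               g1_rate(cc, stressed = FALSE, params = rec))
  }
})

test_that("multiplicative environmental coupling scales the G1 rate", {
  pm <- cambium_params(g1_env_coupling = "multiplicative")
  expect_equal(g1_rate(0.4, gr_today = 0.25, params = pm),
               0.25 * g1_rate(0.4, params = p))
})

test_that("the initial cell's constant rate spans D_init to D_div in d_init", {
  expect_equal(initial_linear_rate(cambium_params(d_init = 7.5)), 1.0)
  expect_equal(initial_linear_rate(cambium_params(d_init = 15)), 0.5)
  expect_error(cambium_params(d_init = 0), "positive")
})

test_that("advance_cell solves phase crossings analytically", {
  cell <- cambial_cell("x", 8.4, 0.5, 1L, p)
  res <- advance_cell(cell, rate = 0.2, time_budget = 1, params = p)
  expect_equal(res$events$type, c("phase_S", "phase_G2"))
  expect_equal(res$events$offset[1], 0.5, tolerance = 1e-12)
  expect_equal(res$events$offset[2], 0.5 + (8.7 - 8.5) / 0.68,
               tolerance = 1e-12)
  expect_equal(res$cell$diameter, 8.7 + 0.68 * (1 - res$events$offset[2]),
               tolerance = 1e-12)
  expect_equal(res$cell$diameter, 8.84, tolerance = 1e-12)
  expect_equal(res$cell$phase, "G2")
})

test_that("a zero rate leaves a G1 cell unchanged", {
  cell <- cambial_cell("x", 5, 0.5, 1L, p)
  res <- advance_cell(cell, rate = 0, time_budget = 2, params = p)
  expect_equal(res$cell$diameter, 5)
  expect_equal(nrow(res$events), 0L)
})

test_that("an M-phase cell stops at the division diameter", {
  cell <- cambial_cell("x", 9.4, 0.5, 1L, p)
  res <- advance_cell(cell, rate = p$V0, time_budget = 1, params = p)
  expect_equal(res$events$type, "ready_to_divide")
  expect_equal(res$events$offset, (9.5 - 9.4) / 0.68, tolerance = 1e-12)
  expect_equal(res$cell$diameter, p$D_div)
})

test_that("phases follow G1->S->G2->M and the diameter never decreases", {
  cell <- cambial_cell("x", 4.75, 2, 1L, p)
  res <- advance_cell(cell, rate = 0.9, time_budget = 30, params = p)
  expect_equal(res$events$type,
               c("phase_S", "phase_G2", "phase_M", "ready_to_divide"))
  expect_true(all(diff(res$events$offset) > 0))
  expect_true(all(diff(res$events$diameter) > 0))
})

test_that("division halves the diameter and partitions the inhibitor", {
  mother <- cambial_cell("0", p$D_div, 1.0, 0L, p)
  d <- divide_cell(mother, alpha = p$alpha, params = p)
  expect_equal(d$proximal$inhibitor, 0.8286)
  expect_equal(d$distal$inhibitor, 1 - 0.8286)
  expect_equal(d$proximal$diameter, 4.75)
  expect_equal(d$distal$diameter, 4.75)
  expect_equal(d$proximal$position, 0L)
  expect_equal(d$distal$position, 1L)
  expect_equal(d$proximal$phase, "G1")
  expect_equal(d$proximal$id, "0.p")
  expect_equal(d$distal$mother_id, "0")

  sym <- divide_cell(mother, alpha = 0.5, params = p)
  expect_equal(sym$proximal$inhibitor, sym$distal$inhibitor)
})

test_that("inhibitor is conserved exactly at division, any alpha", {
  set.seed(3)
  for (k in 1:50) {
    a <- runif(1, 0.01, 0.99)
    inh <- runif(1, 0.3, 5)
    mother <- cambial_cell("m", p$D_div, inh, 2L, p)
    d <- divide_cell(mother, alpha = a, params = p)
    expect_equal(d$proximal$inhibitor + d$distal$inhibitor, inh,
                 tolerance = 1e-12)
    expect_equal(d$proximal$diameter, mother$diameter / 2)
  }
})

test_that("daughter concentrations are 2*alpha and 2*(1-alpha) of mother's", {
  mother <- cambial_cell("m", p$D_div, 1.7, 1L, p)
  cm <- concentration(mother$inhibitor, mother$diameter)
  d <- divide_cell(mother, alpha = p$alpha, params = p)
  expect_equal(concentration(d$proximal$inhibitor, d$proximal$diameter) / cm,
               2 * p$alpha, tolerance = 1e-12)
  expect_equal(concentration(d$distal$inhibitor, d$distal$diameter) / cm,
               2 * (1 - p$alpha), tolerance = 1e-12)
  expect_equal(2 * (1 - p$alpha), 0.343, tolerance = 1e-3)
  expect_equal(2 * p$alpha, 1.657, tolerance = 1e-3)
})

test_that("division below the concentration threshold is refused", {
  mother <- cambial_cell("m", p$D_div, 0.2, 1L, p)  # C = 0.021 < 0.03
  expect_error(divide_cell(mother, alpha = p$alpha, params = p), "exit")
})

test_that("exit rule is strict at the threshold and vacuous at C_min = 0", {
  cell <- cambial_cell("a", 9.5, 0.029 * 9.5, 1L, p)  # C = 0.029 < 0.03
  expect_true(should_exit(cell, p))
  exact <- cambial_cell("b", 9.5, 0.03 * 9.5, 1L, p)
  expect_false(should_exit(exact, p))
  p0 <- p; p0$C_min <- 1e-300   # effectively zero threshold
  expect_false(should_exit(cell, p0))
})

test_that("parameter invariants are enforced", {
  expect_error(cambium_params(D_S = 1.5), "ordered")
  expect_error(cambium_params(alpha = 1), "alpha")
  expect_error(cambium_params(V0 = 0), "V0")
  expect_error(update_params(p, nonsense = 1), "unknown")
  expect_equal(update_params(p, alpha = 0.5)$alpha, 0.5)
})
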