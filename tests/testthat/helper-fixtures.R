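# Deterministic fixtures used across test files.

# Noise-free sinusoidal bell season (the canonical synthetic forcing).
make_bell_series <- function(n_days = 159, peak = 0.8, exponent = 2,
                             doy_start = 127, year = NA) {
  x <- seq(0, 1, length.out = n_days)
  growth_series(year, doy_start, doy_start + n_days - 1L,
                peak * sin(pi * x)^exponent)
}

# Small random-but-reproducible season for property loops.
make_random_series <- function(n_days, seed, year = NA) {
  set.seed(seed)
  x <- seq(0, 1, length.out = n_days)
  base <- runif(1, 0.5, 0.95) * sin(pi * x)^runif(1, 1.5, 3)
  r <- pmin(pmax(base + rnorm(n_days, sd = 0.04), 0), 1)
  growth_series(year, 127, 127 + n_days - 1L, r)
}

write_series_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
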