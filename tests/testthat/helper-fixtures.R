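# Shared fixtures, built in code.

# Tiny hand-enumerable panel: 3 farms x up to 4 consecutive months with
# pre-computed geometric means (no sample columns).
tiny_panel <- function() {
  tibble::tibble(
    farm_id = c(rep("a", 4), rep("b", 4), c("c", "c", "c")),
    year = c(rep(2015, 4), rep(2015, 4), 2015, 2015, 2015),
    month = c(1:4, 1:4, c(1, 2, 4)),   # farm c has a gap at month 3
    geo_mean = c(
      150000, 180000, 210000, 190000,   # a: class 1,1,2,1
      350000, 390000, 410000, 520000,   # b: class 2,2,3,4
      120000, 130000, 160000            # c: class 1 throughout
    )
  )
}

# Deterministic seasonal + trend + noiseless config for exact checks.
degenerate_config <- function(...) {
  synthetic_config(
    n_farms = 2, n_months = 24, seasonal_amplitude = 0, ar_coefficient = 0,
    ar_sd = 0, trend = 0, within_month_cv = 0, farm_sdlog = 0,
    samples_per_month = c(3, 3), ...
  )
}

# Simulate a SARIMA(1,1,0)(1,1,0)12 series with known coefficients by
# filtering white noise and inverting the differences; independent of
# fit_sarima()'s internals.
simulate_sarima_110_110 <- function(n, ar = 0.5, sar = -0.4, sd = 0.04,
                                    level = log(300000)) {
  burn <- 48
  m <- n + burn
  a <- stats::rnorm(m, 0, sd)
  w <- numeric(m)
  for (t in seq_len(m)) {
    w[t] <- a[t] +
      (if (t > 1) ar * w[t - 1] else 0) +
      (if (t > 12) sar * w[t - 12] else 0) -
      (if (t > 13) ar * sar * w[t - 13] else 0)
  }
  x <- diffinv(diffinv(w, lag = 12), lag = 1)
  exp(level + tail(x, n) - mean(tail(x, n)))
}
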