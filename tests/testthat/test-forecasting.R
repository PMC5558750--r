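test_that("complete-record selection matches a per-farm month tally", {
  panel <- enrich_panel(tiny_panel())   # farm c misses month 3 of 4
  sel <- select_complete_farms(panel)
  expect_setequal(sel$farm_id, c("a", "b"))
  # oracle: tally months per farm directly
  tally <- table(panel$farm_id)
  expect_setequal(sel$farm_id, names(tally)[tally == 4])
  a <- dplyr::filter(panel, farm_id == "a")
  expect_equal(sel$period_geo_mean[sel$farm_id == "a"],
               prod(a$geo_mean)^(1 / 4))
  expect_equal(sel$class_index[sel$farm_id == "a"],
               assign_class(prod(a$geo_mean)^(1 / 4)))

  complete <- dplyr::filter(panel, farm_id != "c")
  expect_setequal(select_complete_farms(complete)$farm_id, c("a", "b"))
  # complementary gaps: no farm covers every panel month
  gappy <- enrich_panel(tibble::tibble(
    farm_id = c("g", "g", "h", "h"), year = 2015,
    month = c(1, 2, 2, 3), geo_mean = rep(200000, 4)
  ))
  expect_error(select_complete_farms(gappy),
               class = "sccpay_empty_selection")
})

test_that("class series are per-month cross-farm geometric means", {
  panel <- enrich_panel(tiny_panel())
  sel <- select_complete_farms(panel)
  # farm a alone is class 1: its series is its own
  s1 <- build_class_series(panel, sel, unique(sel$class_index[sel$farm_id == "a"]))
  a <- dplyr::filter(panel, farm_id == "a")
  expect_equal(s1$value, a$geo_mean)
  expect_equal(s1$n_farms, rep(1L, 4))

  two <- enrich_panel(tibble::tibble(
    farm_id = rep(c("p", "q"), each = 3), year = 2015, month = rep(1:3, 2),
    geo_mean = rep(c(160000, 250000), each = 3)
  ))
  selpq <- tibble::tibble(farm_id = c("p", "q"), class_index = 1L)
  spq <- build_class_series(two, selpq, 1)
  expect_equal(spq$value, rep(sqrt(160000 * 250000), 3))

  expect_error(build_class_series(panel, sel, 5),
               class = "sccpay_invalid_input")
})

test_that("the five reference SARIMA orders fit a synthetic 60-month series", {
  withr::with_seed(21, {
    y <- simulate_sarima_110_110(60)
    for (sp in reference_sarima_specs()) {
      fit <- fit_sarima(y, sp, log = TRUE)
      expect_s3_class(fit, "sarima_fit")
      expect_true(is.finite(fit$aic))
      expect_true(fit$ljung_box_p >= 0 && fit$ljung_box_p <= 1)
    }
  })
})

test_that("d=1, D=1 differencing removes a trend-plus-seasonal structure exactly", {
  t <- 1:72
  x <- 300000 + 500 * t + 20000 * cos(2 * pi * t / 12)
  fit <- fit_sarima(x, sarima_spec(0, 1, 0, 0, 1, 0))
  expect_lt(sqrt(fit$model$sigma2), 1e-4 * sd(x))
  fc <- forecast_sarima(fit, 12)
  expect_equal(fc$point,
               300000 + 500 * (73:84) + 20000 * cos(2 * pi * (73:84) / 12),
               tolerance = 1e-6)
})

test_that("series shorter than the identifiability floor are rejected", {
  expect_error(fit_sarima(rnorm(20, 100, 1) + 300,
                          sarima_spec(1, 1, 0, 1, 1, 0)),
               class = "sccpay_invalid_input")
})

test_that("white noise passes the Ljung-Box screen under the null model", {
  withr::with_seed(5, {
    y <- exp(rnorm(60, log(300000), 0.05))
    fit <- fit_sarima(y, sarima_spec(0, 0, 0, 0, 0, 0))
    expect_gt(fit$ljung_box_p, 0.05)
  })
})

test_that("simulated SARIMA coefficients are recovered within 2 SE", {
  withr::with_seed(31, {
    y <- simulate_sarima_110_110(120, ar = 0.5, sar = -0.4, sd = 0.04)
    fit <- fit_sarima(y, sarima_spec(1, 1, 0, 1, 1, 0), log = TRUE)
    td <- tidy(fit)
    expect_equal(td$term, c("ar1", "sar1"))
    expect_true(all(abs(td$estimate - c(0.5, -0.4)) < 2 * td$std.error))
  })
})

test_that("forecast errors accumulate with horizon and refits are reproducible", {
  withr::with_seed(13, {
    y <- simulate_sarima_110_110(72)
    fit <- fit_sarima(y, sarima_spec(1, 1, 0, 1, 1, 0), log = TRUE)
    fc <- forecast_sarima(fit, 12)
    expect_true(all(diff(fc$se) >= -1e-12))
    expect_gt(fc$se[12], fc$se[1])
    expect_true(all(fc$point > 0))
    expect_true(all(fc$lower <= fc$point & fc$point <= fc$upper))
    refit <- fit_sarima(y, sarima_spec(1, 1, 0, 1, 1, 0), log = TRUE)
    expect_identical(forecast_sarima(refit, 12), fc)
    expect_error(forecast_sarima(fit, 0))
  })
})

test_that("order selection prefers parsimonious truth and honours the whiteness screen", {
  withr::with_seed(77, {
    y <- simulate_sarima_110_110(96)
    single <- select_spec(y, list(sarima_spec(1, 1, 0, 1, 1, 0)), log = TRUE)
    expect_equal(format(single$spec), "SARIMA(1,1,0)(1,1,0)[12]")

    wins <- 0
    for (i in 1:8) {
      yy <- simulate_sarima_110_110(96)
      best <- select_spec(
        yy,
        list(true = sarima_spec(1, 1, 0, 1, 1, 0),
             over = sarima_spec(2, 1, 1, 1, 1, 1)),
        log = TRUE
      )
      cand <- attr(best, "candidates")
      if (cand$bic[1] < cand$bic[2] || !cand$converged[2]) wins <- wins + 1
    }
    expect_gt(wins, 4)   # BIC prefers the true model in a majority of runs
  })
})

test_that("the periodogram flags a 12-month seasonal peak", {
  t <- 1:120
  x <- 300000 + 30000 * cos(2 * pi * t / 12) + rnorm(120, 0, 1000)
  pg <- series_periodogram(x)
  expect_equal(pg$period[which.max(pg$spec)], 12, tolerance = 0.05)
})

test_that("reference forecasts carry 12 months per class in cells/mL", {
  rf <- reference_forecasts()
  expect_equal(nrow(rf), 60)
  expect_equal(unname(table(rf$class_index)), rep(12L, 5), ignore_attr = TRUE)
  expect_equal(rf$point[rf$class_index == 1 & rf$month == 1], 206000)
  expect_equal(rf$se[rf$class_index == 5 & rf$month == 12], 133000)
  # the forecast-table writer round-trips through the packaged CSV
  path <- system.file("extdata", "reference_forecasts_2016.csv",
                      package = "sccpay")
  wide <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(wide$point_class3[7], rf$point[rf$class_index == 3 & rf$month == 7])
})
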