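test_that("quadrant grids have the 20/20/10/30 layout", {
  expect_equal(nrow(build_grid(1)), 20)
  expect_equal(nrow(build_grid(2)), 20)
  expect_equal(nrow(build_grid(3)), 10)
  expect_equal(nrow(build_grid(4)), 30)
  expect_equal(sum(vapply(1:4, \(k) nrow(build_grid(k)), 1)), 80)
  expect_error(build_grid(5), class = "sccpay_unsupported_class")
  # mean bins tile the class interval in 50,000 steps; SD bins are the five
  # 50,000-step bands with an open top
  g2 <- build_grid(2)
  expect_equal(sort(unique(g2$mean_hi)), c(250, 300, 350, 400) * 1000)
  expect_equal(min(g2$mean_lo), 200000)
  expect_equal(sort(unique(g2$sd_hi)), c(50, 100, 150, 200, Inf) * 1000)
})

test_that("quadrant placement is upper-inclusive and matches the worked case", {
  g1 <- build_grid(1)
  expect_equal(assign_quadrant(140000, 15000, g1),
               tibble::tibble(mean_bin = 3L, sd_bin = 1L))
  expect_equal(assign_quadrant(150000, 50000, g1),
               tibble::tibble(mean_bin = 3L, sd_bin = 1L))
  expect_equal(assign_quadrant(140000, 250000, g1)$sd_bin, 5L)
  expect_error(assign_quadrant(250000, 0, g1), class = "sccpay_out_of_class")
})

test_that("empirical change probabilities equal a brute-force recount", {
  panel <- enrich_panel(tiny_panel())
  cells <- empirical_change_probabilities(panel)

  # independent oracle: loop over all farm-month rows, re-derive eligibility,
  # change flags and quadrant coordinates from scratch
  oracle_n <- list(); oracle_ch <- list()
  for (i in seq_len(nrow(panel))) {
    r <- panel[i, ]
    nxt <- panel[panel$farm_id == r$farm_id & panel$year == r$year &
                   panel$month == r$month + 1, ]
    if (is.na(r$est_sd) || nrow(nxt) != 1 || r$class_index > 4) next
    sd_bin <- min(which(r$est_sd <= c(50, 100, 150, 200, Inf) * 1000))
    lo <- c(0, 200, 400, 500)[r$class_index] * 1000
    mean_bin <- ceiling((r$geo_mean - lo) / 50000)
    key <- paste(r$class_index, mean_bin, sd_bin)
    oracle_n[[key]] <- (oracle_n[[key]] %||% 0) + 1
    oracle_ch[[key]] <- (oracle_ch[[key]] %||% 0) +
      (nxt$class_index > r$class_index)
  }
  for (key in names(oracle_n)) {
    parts <- as.integer(strsplit(key, " ")[[1]])
    row <- cells[cells$class_index == parts[1] & cells$mean_bin == parts[2] &
                   cells$sd_bin == parts[3], ]
    expect_equal(row$n_obs, oracle_n[[key]])
    expect_equal(row$n_changed, oracle_ch[[key]])
    expect_equal(row$probability, 100 * oracle_ch[[key]] / oracle_n[[key]])
  }
  expect_equal(sum(cells$n_obs), sum(unlist(oracle_n)))
  # unoccupied quadrants carry no probability
  expect_true(all(is.na(cells$probability[cells$n_obs == 0])))
})

test_that("degenerate panels give all-100% and all-0% cells", {
  up <- enrich_panel(tibble::tibble(
    farm_id = rep(c("u", "v"), each = 3), year = 2015,
    month = rep(1:3, 2),
    geo_mean = c(140000, 150000, 250000, 340000, 350000, 450000)
  ))
  cells <- empirical_change_probabilities(up)
  occ <- cells[cells$n_obs > 0, ]
  expect_true(all(occ$probability == 100))

  down <- enrich_panel(tibble::tibble(
    farm_id = rep("w", 3), year = 2015, month = 1:3,
    geo_mean = c(450000, 440000, 430000)
  ))
  cells2 <- empirical_change_probabilities(down)
  expect_true(all(cells2$probability[cells2$n_obs > 0] == 0))
})

test_that("noise-free linear cells are fit exactly", {
  g <- build_grid(1)
  cells <- g |>
    dplyr::mutate(
      median_mean = (mean_lo + mean_hi) / 2,
      median_sd = ifelse(is.finite(sd_hi), (sd_lo + sd_hi) / 2, 225000),
      n_obs = 10L, n_changed = 5L,
      probability = 10 + 1e-4 * median_mean + 5e-5 * median_sd
    )
  m <- fit_change_model(cells, 1, log10_response = FALSE)
  expect_equal(unname(m$coefficients), c(10, 1e-4, 5e-5), tolerance = 1e-8)
  expect_equal(glance(m)$adj.r.squared, 1, tolerance = 1e-8)
  td <- tidy(m)
  expect_equal(td$term, c("(Intercept)", "median_mean", "median_sd"))
  expect_true(all(td$vif[-1] < 5))
})

test_that("known coefficients are recovered from noisy synthetic quadrants", {
  withr::with_seed(101, {
    b <- c(0.66, 2.27e-6, 9.69e-7)  # log10-scale truth, class 2 layout
    cells <- build_grid(2) |>
      dplyr::mutate(
        median_mean = (mean_lo + mean_hi) / 2,
        median_sd = ifelse(is.finite(sd_hi), (sd_lo + sd_hi) / 2, 225000),
        n_obs = 25L,
        probability = 10^(b[1] + b[2] * median_mean + b[3] * median_sd +
                            rnorm(dplyr::n(), 0, 0.02)),
        n_changed = as.integer(round(n_obs * probability / 100))
      )
    m <- fit_change_model(cells, 2)
    td <- tidy(m)
    expect_true(all(abs(td$estimate - b) < 3 * td$std.error))
    expect_true(m$log10_response)
  })
})

test_that("zero-probability cells are dropped from log10 fits with a warning", {
  cells <- build_grid(2) |>
    dplyr::mutate(
      median_mean = (mean_lo + mean_hi) / 2,
      median_sd = ifelse(is.finite(sd_hi), (sd_lo + sd_hi) / 2, 225000),
      n_obs = 10L,
      probability = 10^(0.5 + 2e-6 * median_mean),
      n_changed = 1L
    )
  cells$probability[1:3] <- 0
  expect_warning(m <- fit_change_model(cells, 2), "probability 0")
  expect_equal(m$n_dropped_zero, 3L)
  expect_equal(m$n_cells, 17L)
})

test_that("perfectly collinear predictors are rejected", {
  cells <- build_grid(3) |>
    dplyr::mutate(
      median_mean = (mean_lo + mean_hi) / 2,
      median_sd = 2 * median_mean,     # exact collinearity
      n_obs = 10L, n_changed = 2L, probability = 20
    )
  expect_error(fit_change_model(cells, 3), class = "sccpay_singular_fit")
})

test_that("published equations reproduce the printed predictions", {
  # class-2 worked example: mean 350,000, SD 31,028 -> 31%
  expect_equal(round(predict_change_probability(350000, 31028)), 31)
  expect_equal(predict_change_probability(350000, 31028),
               10^(0.66 + 2.27e-6 * 350000 + 9.69e-7 * 31028),
               tolerance = 1e-12)
  # class-1 equation at mean 100,000, SD 0: 11.87 + 18.3 = 30.17
  expect_equal(predict_change_probability(100000, 0), 30.17,
               tolerance = 1e-10)
  # clamping at 100%
  expect_equal(predict_change_probability(200000, 1e6), 100)
  expect_error(predict_change_probability(900000, 10000),
               class = "sccpay_unsupported_class")
})

test_that("predicted probability is monotone in the printed coefficient signs", {
  means <- seq(210000, 395000, by = 5000)
  p <- predict_change_probability(means, rep(40000, length(means)))
  expect_true(all(diff(p) > 0))
  sds <- seq(0, 200000, by = 10000)
  p2 <- predict_change_probability(rep(300000, length(sds)), sds)
  expect_true(all(diff(p2) > 0))
  p1 <- predict_change_probability(seq(50000, 200000, 10000), rep(1000, 16))
  expect_true(all(diff(p1) > 0))
  # class 4 increases in mean
  m4 <- seq(510000, 790000, 20000)
  p4 <- predict_change_probability(m4, rep(50000, length(m4)))
  expect_true(all(diff(p4) > 0))
})

test_that("a fitted model predicts through the same back-transform path", {
  withr::with_seed(7, {
    cells <- build_grid(1) |>
      dplyr::mutate(
        median_mean = (mean_lo + mean_hi) / 2,
        median_sd = ifelse(is.finite(sd_hi), (sd_lo + sd_hi) / 2, 225000),
        n_obs = 10L, n_changed = 3L,
        probability = 5 + 1e-4 * median_mean + 4e-5 * median_sd
      )
    m <- fit_change_model(cells, 1)
    expect_equal(predict_change_probability(120000, 60000, model = m),
                 5 + 1e-4 * 120000 + 4e-5 * 60000, tolerance = 1e-6)
    expect_error(predict_change_probability(250000, 1000, model = m),
                 class = "sccpay_invalid_input")
  })
})

test_that("diagnostics expose residual series and VIFs for plotting", {
  cells <- build_grid(2) |>
    dplyr::mutate(
      median_mean = (mean_lo + mean_hi) / 2,
      median_sd = ifelse(is.finite(sd_hi), (sd_lo + sd_hi) / 2, 225000),
      n_obs = 10L, n_changed = 2L,
      probability = 10^(0.4 + 2e-6 * median_mean + 1e-6 * median_sd)
    )
  m <- fit_change_model(cells, 2)
  d <- change_model_diagnostics(m)
  expect_equal(nrow(d$series), m$n_cells)
  expect_named(d$vif, c("median_mean", "median_sd"))
  expect_s3_class(plot_change_model_diagnostics(m), "ggplot")
  expect_s3_class(plot_quadrants(
    empirical_change_probabilities(enrich_panel(tiny_panel()))), "ggplot")
})
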