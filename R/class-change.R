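# Quadrant construction, empirical class-change probabilities and the
# mean/SD regression that predicts them.

mean_bin_uppers_kcells <- list(
  `1` = c(50, 100, 150, 200),
  `2` = c(250, 300, 350, 400),
  `3` = c(450, 500),
  `4` = c(550, 600, 650, 700, 750, 800)
)
sd_bin_uppers_kcells <- c(50, 100, 150, 200, Inf)

#' Quadrant grid for a payment class
#'
#' Within each of classes 1-4 the (monthly mean, estimated SD) plane is cut
#' into quadrants: the mean axis in 50,000 cells/mL steps across the class's
#' BTSCC range (4, 4, 2 and 6 bins for classes 1-4) and the SD axis into five
#' bins (<=50k, 50-100k, 100-150k, 150-200k, >200k), giving 20, 20, 10 and 30
#' quadrants. Class 5 has no worse class to fall into, so no grid exists
#' for it.
#'
#' All bins are upper-inclusive: a mean of exactly 150,000 belongs to the
#' 100-150k bin, an SD of exactly 50,000 to the <=50k bin.
#'
#' @param class_index Payment class, 1-4.
#' @return Tibble with one row per quadrant: `class_index`, `mean_bin`,
#'   `sd_bin` (integer coordinates) and the bin edges `mean_lo`, `mean_hi`,
#'   `sd_lo`, `sd_hi` in cells/mL (lower edges exclusive, upper inclusive).
#' @examples
#' nrow(build_grid(4))  # 30
#' @export
build_grid <- function(class_index) {
  stopifnot(length(class_index) == 1)
  if (!class_index %in% 1:4) {
    rlang::abort(
      "quadrant grids exist only for classes 1-4 (no class is worse than 5).",
      class = "sccpay_unsupported_class"
    )
  }
  m_up <- mean_bin_uppers_kcells[[as.character(class_index)]] * 1000
  m_lo <- c(payment_scheme()$lower_kcells[class_index] * 1000 - 1000,
            utils::head(m_up, -1))
  s_up <- sd_bin_uppers_kcells * 1000
  s_lo <- c(0, utils::head(s_up, -1))
  tidyr::expand_grid(
    mean_bin = seq_along(m_up),
    sd_bin = seq_along(s_up)
  ) |>
    dplyr::mutate(
      class_index = as.integer(class_index),
      mean_lo = m_lo[.data$mean_bin], mean_hi = m_up[.data$mean_bin],
      sd_lo = s_lo[.data$sd_bin], sd_hi = s_up[.data$sd_bin],
      .before = 1
    ) |>
    dplyr::relocate("class_index")
}

#' Locate a (mean, SD) pair in its class's quadrant grid
#'
#' @param mean,sd Numeric vectors: monthly geometric mean and moving-range SD,
#'   cells/mL. The means must lie inside the class interval of `grid`.
#' @param grid A grid from [build_grid()].
#' @return Tibble with `mean_bin` and `sd_bin` integer coordinates.
#' @examples
#' assign_quadrant(140000, 15000, build_grid(1))  # mean_bin 3, sd_bin 1
#' @export
assign_quadrant <- function(mean, sd, grid) {
  stopifnot(length(mean) == length(sd), all(sd >= 0))
  class_index <- grid$class_index[1]
  m_up <- sort(unique(grid$mean_hi))
  m_lo0 <- min(grid$mean_lo)
  if (any(mean <= m_lo0) || any(mean > max(m_up))) {
    rlang::abort(
      sprintf("mean outside the class %d interval (%s, %s] cells/mL.",
              class_index, format(m_lo0), format(max(m_up))),
      class = "sccpay_out_of_class"
    )
  }
  s_up <- sort(unique(grid$sd_hi))
  tibble::tibble(
    mean_bin = findInterval(mean, utils::head(m_up, -1), left.open = TRUE) + 1L,
    sd_bin = findInterval(sd, utils::head(s_up, -1), left.open = TRUE) + 1L
  )
}

#' Empirical probabilities of dropping to a worse payment class
#'
#' For every quadrant of classes 1-4, computes the proportion of farm-months
#' whose payment class in the immediately following calendar month was
#' strictly worse (higher index), together with the medians of the
#' contributing monthly means and moving-range SDs — the three data points
#' per quadrant that feed the regression in [fit_change_model()].
#'
#' A farm-month contributes when its moving-range SD is defined (the previous
#' calendar month has a record) and the next calendar month has a record;
#' a farm that stays in one quadrant for several months contributes one
#' observation per month. Farm-months adjacent to gaps are excluded from the
#' denominators.
#'
#' @param panel Enriched panel (see [enrich_panel()]) with `geo_mean`,
#'   `est_sd`, `class_index`.
#' @param scheme A `sccpay_scheme`.
#' @return Tibble with one row per quadrant of classes 1-4 (all 80 under the
#'   default grid): bin coordinates and edges, `n_obs`, `n_changed`,
#'   `probability` (percent, `NA` where `n_obs` is 0), `median_mean`,
#'   `median_sd`.
#' @export
empirical_change_probabilities <- function(panel, scheme = payment_scheme()) {
  stopifnot(all(c("farm_id", "year", "month", "geo_mean", "est_sd",
                  "class_index") %in% names(panel)))
  obs <- panel |>
    dplyr::mutate(.midx = month_index(.data$year, .data$month)) |>
    dplyr::arrange(.data$farm_id, .data$.midx) |>
    dplyr::group_by(.data$farm_id) |>
    dplyr::mutate(
      next_class = dplyr::if_else(
        dplyr::lead(.data$.midx) - .data$.midx == 1L,
        dplyr::lead(.data$class_index), NA_integer_
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(
      !is.na(.data$est_sd), !is.na(.data$next_class),
      .data$class_index %in% 1:4
    ) |>
    dplyr::mutate(changed = .data$next_class > .data$class_index)

  cells_for_class <- function(k) {
    grid <- build_grid(k)
    sub <- dplyr::filter(obs, .data$class_index == k)
    if (nrow(sub) > 0) {
      sub <- dplyr::bind_cols(
        sub, assign_quadrant(sub$geo_mean, sub$est_sd, grid)
      )
      counts <- sub |>
        dplyr::group_by(.data$mean_bin, .data$sd_bin) |>
        dplyr::summarise(
          n_obs = dplyr::n(),
          n_changed = sum(.data$changed),
          median_mean = stats::median(.data$geo_mean),
          median_sd = stats::median(.data$est_sd),
          .groups = "drop"
        )
    } else {
      counts <- tibble::tibble(
        mean_bin = integer(), sd_bin = integer(), n_obs = integer(),
        n_changed = integer(), median_mean = double(), median_sd = double()
      )
    }
    grid |>
      dplyr::left_join(counts, by = c("mean_bin", "sd_bin")) |>
      dplyr::mutate(
        n_obs = dplyr::coalesce(.data$n_obs, 0L),
        n_changed = dplyr::coalesce(.data$n_changed, 0L),
        probability = dplyr::if_else(
          .data$n_obs > 0, 100 * .data$n_changed / .data$n_obs, NA_real_
        )
      )
  }

  purrr::map(1:4, cells_for_class) |>
    purrr::list_rbind() |>
    dplyr::relocate("probability", .after = "n_changed")
}

#' Fit the quadrant regression of class-change probability on mean and SD
#'
#' Ordinary least squares of the quadrant class-change probability (percent)
#' on the quadrant medians of the monthly BTSCC mean and moving-range SD.
#' For classes 2-4 the response is log10-transformed (the scale on which the
#' published class 2-4 equations live; predictions back-transform as powers
#' of 10); class 1 is fit untransformed. Quadrants with zero observations are
#' excluded; under the log transform, quadrants with probability exactly 0
#' cannot enter and are dropped with a warning.
#'
#' @param cells Quadrant tibble from [empirical_change_probabilities()].
#' @param class_index Class to fit, 1-4.
#' @param log10_response Transform the response? Defaults to the published
#'   convention: `FALSE` for class 1, `TRUE` for classes 2-4.
#' @param min_n Minimum `n_obs` for a quadrant to enter the fit (default 1).
#' @return An object of class `class_change_model`: the coefficient triple
#'   (intercept, mean, SD), their standard errors and p-values, adjusted R2,
#'   VIFs of the two predictors, and the underlying `lm` fit. Use
#'   [generics::tidy()] / [generics::glance()] to extract tables and
#'   [predict_change_probability()] to predict.
#' @export
fit_change_model <- function(cells, class_index,
                             log10_response = class_index >= 2,
                             min_n = 1) {
  stopifnot(class_index %in% 1:4)
  dat <- cells |>
    dplyr::filter(.data$class_index == !!class_index,
                  .data$n_obs >= min_n, !is.na(.data$probability))
  n_zero <- 0L
  if (log10_response) {
    n_zero <- sum(dat$probability == 0)
    if (n_zero > 0) {
      rlang::warn(sprintf(
        "dropping %d quadrant(s) with probability 0 from the log10 fit.",
        n_zero
      ))
      dat <- dplyr::filter(dat, .data$probability > 0)
    }
    dat$.y <- log10(dat$probability)
  } else {
    dat$.y <- dat$probability
  }
  if (nrow(dat) < 4) {
    abort_bad_input("need at least 4 usable quadrants to fit the regression.")
  }
  fit <- stats::lm(.y ~ median_mean + median_sd, data = dat)
  if (fit$rank < 3) {
    rlang::abort("rank-deficient quadrant design (collinear predictors).",
                 class = "sccpay_singular_fit")
  }
  vifs <- tryCatch(car::vif(fit), error = function(e) c(
    median_mean = Inf, median_sd = Inf
  ))
  structure(
    list(
      class_index = as.integer(class_index),
      log10_response = log10_response,
      coefficients = stats::coef(fit),
      fit = fit,
      vif = vifs,
      n_cells = nrow(dat),
      n_dropped_zero = n_zero
    ),
    class = "class_change_model"
  )
}

#' @export
print.class_change_model <- function(x, ...) {
  cat(sprintf(
    "Class-change regression for class %d (%s response), %d quadrants\n",
    x$class_index, if (x$log10_response) "log10" else "untransformed",
    x$n_cells
  ))
  print(generics::tidy(x))
  invisible(x)
}

#' Tidy a class-change regression
#'
#' @param x A `class_change_model`.
#' @param ... Unused.
#' @return Tibble with one row per term: estimate, standard error, statistic,
#'   p-value, and the VIF for the two predictors.
#' @export
tidy.class_change_model <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, 1],
    std.error = sm[, 2],
    statistic = sm[, 3],
    p.value = sm[, 4],
    vif = c(NA_real_, unname(x$vif[c("median_mean", "median_sd")]))
  )
}

#' Model-level summary of a class-change regression
#'
#' @param x A `class_change_model`.
#' @param ... Unused.
#' @return One-row tibble: adjusted R2, sigma, number of quadrants used and
#'   dropped, transform flag.
#' @export
glance.class_change_model <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(
    class_index = x$class_index,
    adj.r.squared = sm$adj.r.squared,
    r.squared = sm$r.squared,
    sigma = sm$sigma,
    n_cells = x$n_cells,
    n_dropped_zero = x$n_dropped_zero,
    log10_response = x$log10_response
  )
}

#' Residual diagnostics for graphical assessment
#'
#' The regression assumptions (homoscedasticity, normality, linearity) are
#' assessed graphically, not by automated tests: this returns the series
#' needed for the standard plots — standardized residuals against fitted
#' values and predictors, and normal theoretical quantiles for a Q-Q plot —
#' alongside the VIF table for multicollinearity.
#'
#' @param model A `class_change_model`.
#' @return List with `series` (tibble: fitted, residual, std_residual,
#'   theoretical quantile, median_mean, median_sd) and `vif` (named vector).
#' @export
change_model_diagnostics <- function(model) {
  fit <- model$fit
  r <- stats::rstandard(fit)
  ord <- order(r)
  theo <- numeric(length(r))
  theo[ord] <- stats::qnorm(stats::ppoints(length(r)))
  list(
    series = tibble::tibble(
      fitted = stats::fitted(fit),
      residual = stats::residuals(fit),
      std_residual = r,
      theoretical = theo,
      median_mean = fit$model$median_mean,
      median_sd = fit$model$median_sd
    ),
    vif = model$vif
  )
}

#' Published class-change prediction equations
#'
#' The coefficient triples of the four predictive equations estimated on the
#' Brazilian national BTSCC database: probability (percent, directly for
#' class 1; as a power of 10 for classes 2-4) as a linear function of the
#' farm's monthly mean and moving-range SD (both cells/mL).
#'
#' @return Tibble with `class_index`, `beta0`, `beta_mean`, `beta_sd`,
#'   `log10_response`.
#' @examples
#' published_equations()
#' @export
published_equations <- function() {
  tibble::tibble(
    class_index = 1:4,
    beta0 = c(11.87, 0.66, 0.52, -0.05),
    beta_mean = c(1.83e-4, 2.27e-6, 2.32e-6, 2.07e-6),
    beta_sd = c(8.39e-5, 9.69e-7, -1.61e-7, 7.37e-8),
    log10_response = c(FALSE, TRUE, TRUE, TRUE)
  )
}

#' Predict the probability of dropping to a worse payment class
#'
#' Evaluates the class-change equation for the class containing each monthly
#' mean: linear predictor `beta0 + beta_mean * mean + beta_sd * sd`, applied
#' directly for class 1 and back-transformed as `10^(.)` for classes 2-4,
#' then clamped to [0, 100] percent. Defaults to the published equations;
#' pass a fitted [fit_change_model()] object to use your own fit (its class
#' must match the mean's class). Values are returned at full precision;
#' conventionally reported rounded to the whole percent.
#'
#' @param mean,sd Monthly geometric mean and moving-range SD, cells/mL.
#' @param model `NULL` (use [published_equations()]), a tibble in the
#'   [published_equations()] layout, or a `class_change_model`.
#' @param scheme A `sccpay_scheme` used to locate each mean's class.
#' @return Numeric vector of probabilities in percent.
#' @examples
#' round(predict_change_probability(350000, 31028))  # 31
#' @export
predict_change_probability <- function(mean, sd, model = NULL,
                                       scheme = payment_scheme()) {
  stopifnot(length(mean) == length(sd), all(sd >= 0))
  cls <- assign_class(mean, scheme)
  if (any(cls > 4)) {
    rlang::abort(
      "no class-change equation exists for class 5 (no worse class exists).",
      class = "sccpay_unsupported_class"
    )
  }
  if (inherits(model, "class_change_model")) {
    if (any(cls != model$class_index)) {
      abort_bad_input("mean falls outside the fitted model's class.")
    }
    eqs <- tibble::tibble(
      class_index = model$class_index,
      beta0 = model$coefficients[["(Intercept)"]],
      beta_mean = model$coefficients[["median_mean"]],
      beta_sd = model$coefficients[["median_sd"]],
      log10_response = model$log10_response
    )
  } else if (is.null(model)) {
    eqs <- published_equations()
  } else {
    eqs <- model
  }
  i <- match(cls, eqs$class_index)
  lp <- eqs$beta0[i] + eqs$beta_mean[i] * mean + eqs$beta_sd[i] * sd
  p <- ifelse(eqs$log10_response[i], 10^lp, lp)
  pmin(pmax(p, 0), 100)
}
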