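# Class-level BTSCC series and seasonal ARIMA forecasting.

#' Select farms with a complete monthly record
#'
#' Time-series modelling uses only farms observed in every month of the study
#' window (e.g. all 60 months of a 5-year design). Each selected farm is
#' tagged with its whole-period geometric mean BTSCC and the payment class of
#' that mean, which determines the class series it contributes to.
#'
#' @param panel Enriched panel with `geo_mean`.
#' @param required_months Number of months a farm must cover; defaults to all
#'   distinct months present in the panel.
#' @param scheme A `sccpay_scheme`.
#' @return Tibble with `farm_id`, `n_months`, `period_geo_mean`,
#'   `class_index`, one row per qualifying farm.
#' @export
select_complete_farms <- function(panel, required_months = NULL,
                                  scheme = payment_scheme()) {
  stopifnot(all(c("farm_id", "year", "month", "geo_mean") %in% names(panel)))
  midx <- month_index(panel$year, panel$month)
  all_months <- sort(unique(midx))
  if (is.null(required_months)) required_months <- length(all_months)
  if (length(all_months) < required_months) {
    abort_bad_input("panel spans fewer months than `required_months`.")
  }
  keep_months <- utils::tail(all_months, required_months)
  sel <- panel |>
    dplyr::mutate(.midx = midx) |>
    dplyr::filter(.data$.midx %in% keep_months) |>
    dplyr::group_by(.data$farm_id) |>
    dplyr::summarise(
      n_months = dplyr::n_distinct(.data$.midx),
      n_records = dplyr::n(),
      period_geo_mean = geometric_mean(.data$geo_mean),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_months == required_months,
                  .data$n_records == required_months) |>
    dplyr::select(-"n_records")
  if (nrow(sel) == 0) {
    rlang::abort("no farm has a complete monthly record.",
                 class = "sccpay_empty_selection")
  }
  dplyr::mutate(sel,
                class_index = assign_class(.data$period_geo_mean, scheme))
}

#' Monthly class-level BTSCC series
#'
#' The per-month cross-farm geometric mean over the farms assigned to one
#' payment class, the series the seasonal ARIMA models are fit to.
#'
#' @param panel Enriched panel.
#' @param farms Selection from [select_complete_farms()].
#' @param class_index Payment class, 1-5.
#' @return Tibble of class `sccpay_class_series`: `year`, `month`, `value`
#'   (cells/mL), `n_farms`; months contiguous and increasing. The class index
#'   is carried in the `class_index` attribute and column.
#' @export
build_class_series <- function(panel, farms, class_index) {
  ids <- farms$farm_id[farms$class_index == class_index]
  if (length(ids) == 0) {
    abort_bad_input(sprintf("no selected farm falls in class %d.", class_index))
  }
  series <- panel |>
    dplyr::filter(.data$farm_id %in% ids) |>
    dplyr::group_by(.data$year, .data$month) |>
    dplyr::summarise(
      value = geometric_mean(.data$geo_mean),
      n_farms = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(month_index(.data$year, .data$month)) |>
    dplyr::mutate(class_index = as.integer(class_index))
  midx <- month_index(series$year, series$month)
  if (!all(diff(midx) == 1L)) {
    abort_bad_input("class series has month gaps; forecasting needs a contiguous series.")
  }
  class(series) <- c("sccpay_class_series", class(series))
  series
}

#' Seasonal ARIMA order
#'
#' @param p,d,q Non-seasonal AR, differencing and MA orders.
#' @param P,D,Q Seasonal AR, differencing and MA orders.
#' @param s Seasonal period; 12 for monthly BTSCC.
#' @return A `sarima_spec` list.
#' @examples
#' sarima_spec(2, 1, 0, 2, 1, 0)
#' @export
sarima_spec <- function(p, d, q, P, D, Q, s = 12) {
  ord <- c(p = p, d = d, q = q, P = P, D = D, Q = Q, s = s)
  stopifnot(all(ord >= 0), all(ord == floor(ord)), s >= 1)
  structure(as.list(ord), class = "sarima_spec")
}

#' @export
format.sarima_spec <- function(x, ...) {
  sprintf("SARIMA(%d,%d,%d)(%d,%d,%d)[%d]", x$p, x$d, x$q, x$P, x$D, x$Q, x$s)
}

#' @export
print.sarima_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Seasonal ARIMA orders used per payment class
#'
#' The model orders selected for the five class-level series in the source
#' analysis: (2,1,0)(2,1,0)12, (2,1,0)(1,1,0)12, (1,1,0)(1,1,0)12,
#' (0,1,1)(0,1,2)12 and (1,1,1)(0,1,1)12 for classes 1-5. Useful as a
#' candidate list for [select_spec()].
#'
#' @return Named list of `sarima_spec`s, one per class.
#' @export
reference_sarima_specs <- function() {
  list(
    class_1 = sarima_spec(2, 1, 0, 2, 1, 0),
    class_2 = sarima_spec(2, 1, 0, 1, 1, 0),
    class_3 = sarima_spec(1, 1, 0, 1, 1, 0),
    class_4 = sarima_spec(0, 1, 1, 0, 1, 2),
    class_5 = sarima_spec(1, 1, 1, 0, 1, 1)
  )
}

series_values <- function(series) {
  if (is.numeric(series)) return(as.numeric(series))
  stopifnot("value" %in% names(series))
  series$value
}

#' Fit a seasonal ARIMA model by maximum likelihood
#'
#' Fits `SARIMA(p,d,q)(P,D,Q)s` to a class-level BTSCC series with
#' [stats::arima()] (method `"ML"`), and attaches the diagnostics used for
#' model assessment: AIC, BIC, the Ljung-Box test of residual whiteness
#' (null: errors uncorrelated; the fit is conventionally accepted when
#' p > 0.05) and the residual ACF/PACF series.
#'
#' @param series A `sccpay_class_series`, a `value`-column tibble, or a
#'   numeric vector (cells/mL; pass logs yourself via `log = TRUE`).
#' @param spec A [sarima_spec()].
#' @param log Fit on log-transformed values (default `FALSE`: raw cells/mL,
#'   giving symmetric forecast errors on the count scale).
#' @param lb_lag Ljung-Box lag; default `min(24, floor(n/5))`, raised if
#'   needed so the test has positive degrees of freedom after subtracting
#'   the `p+q+P+Q` fitted parameters.
#' @return An object of class `sarima_fit` with elements `spec`, `model`
#'   (the `Arima` fit), `aic`, `bic`, `ljung_box_p`, `ljung_box_lag`,
#'   `residual_acf` (tibble: lag, acf, pacf), `n`, `log`. Supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
fit_sarima <- function(series, spec, log = FALSE, lb_lag = NULL) {
  stopifnot(inherits(spec, "sarima_spec"))
  x <- series_values(series)
  n <- length(x)
  floor_n <- 2 * spec$s + spec$d + spec$D * spec$s
  if (n < floor_n) {
    abort_bad_input(sprintf(
      "series too short (%d) for %s: need at least %d observations.",
      n, format(spec), floor_n
    ))
  }
  if (log) x <- base::log(x)
  xt <- stats::ts(x, frequency = spec$s)
  model <- tryCatch(
    stats::arima(xt, order = c(spec$p, spec$d, spec$q),
                 seasonal = list(order = c(spec$P, spec$D, spec$Q),
                                 period = spec$s),
                 method = "ML"),
    error = function(e) {
      rlang::abort(
        sprintf("SARIMA fit %s failed to converge: %s",
                format(spec), conditionMessage(e)),
        class = "sccpay_nonconvergence", parent = e
      )
    }
  )
  res <- stats::residuals(model)
  fitdf <- spec$p + spec$q + spec$P + spec$Q
  lag <- if (is.null(lb_lag)) min(24, floor(n / 5)) else lb_lag
  lag <- max(lag, fitdf + 1)
  lb <- stats::Box.test(res, lag = lag, type = "Ljung-Box", fitdf = fitdf)
  n_par <- length(stats::coef(model)) + 1  # + innovation variance
  max_lag <- min(length(res) - 1, 24)
  acfs <- stats::acf(res, lag.max = max_lag, plot = FALSE)$acf[-1]
  pacfs <- stats::pacf(res, lag.max = max_lag, plot = FALSE)$acf
  structure(
    list(
      spec = spec,
      model = model,
      aic = stats::AIC(model),
      bic = stats::AIC(model, k = base::log(model$nobs)),
      ljung_box_p = unname(lb$p.value),
      ljung_box_lag = lag,
      residual_acf = tibble::tibble(
        lag = seq_len(max_lag), acf = as.numeric(acfs),
        pacf = as.numeric(pacfs)
      ),
      n = n,
      n_par = n_par,
      log = log
    ),
    class = "sarima_fit"
  )
}

#' @export
print.sarima_fit <- function(x, ...) {
  cat(format(x$spec), sprintf(
    " n=%d  AIC=%.1f  BIC=%.1f  Ljung-Box p=%.3f (lag %d)\n",
    x$n, x$aic, x$bic, x$ljung_box_p, x$ljung_box_lag
  ))
  invisible(x)
}

#' Tidy a seasonal ARIMA fit
#' @param x A `sarima_fit`.
#' @param ... Unused.
#' @return Tibble of coefficient estimates and standard errors.
#' @export
tidy.sarima_fit <- function(x, ...) {
  est <- stats::coef(x$model)
  se <- sqrt(pmax(diag(x$model$var.coef), 0))
  tibble::tibble(term = names(est), estimate = unname(est),
                 std.error = unname(se[names(est)]))
}

#' One-row summary of a seasonal ARIMA fit
#' @param x A `sarima_fit`.
#' @param ... Unused.
#' @return Tibble: spec, n, AIC, BIC, Ljung-Box p, residual sd.
#' @export
glance.sarima_fit <- function(x, ...) {
  tibble::tibble(
    spec = format(x$spec), n = x$n, aic = x$aic, bic = x$bic,
    ljung_box_p = x$ljung_box_p,
    sigma = sqrt(x$model$sigma2),
    log_scale = x$log
  )
}

#' Select a seasonal ARIMA order from candidates
#'
#' Fits every candidate order, discards non-converging fits, and among fits
#' whose residuals pass the Ljung-Box whiteness screen (p > 0.05) returns the
#' one minimising AIC, breaking ties by BIC. If no candidate passes the
#' screen, falls back to the minimum-AIC converged fit with a warning.
#'
#' @param series Series as in [fit_sarima()].
#' @param specs List of [sarima_spec()]s.
#' @param lb_alpha Whiteness screen level (default 0.05).
#' @param ... Passed to [fit_sarima()].
#' @return The selected `sarima_fit`; the comparison table (spec, aic, bic,
#'   ljung_box_p, converged) is attached as attribute `"candidates"`.
#' @export
select_spec <- function(series, specs, lb_alpha = 0.05, ...) {
  fits <- purrr::map(specs, function(sp) {
    tryCatch(fit_sarima(series, sp, ...), sccpay_nonconvergence = function(e) NULL)
  })
  tab <- tibble::tibble(
    spec = purrr::map_chr(specs, format),
    converged = !purrr::map_lgl(fits, is.null),
    aic = purrr::map_dbl(fits, \(f) if (is.null(f)) NA_real_ else f$aic),
    bic = purrr::map_dbl(fits, \(f) if (is.null(f)) NA_real_ else f$bic),
    ljung_box_p = purrr::map_dbl(fits, \(f) if (is.null(f)) NA_real_ else f$ljung_box_p)
  )
  ok <- which(tab$converged)
  if (length(ok) == 0) {
    rlang::abort("no candidate SARIMA order converged.",
                 class = "sccpay_nonconvergence")
  }
  white <- ok[tab$ljung_box_p[ok] > lb_alpha]
  pool <- if (length(white) > 0) white else {
    rlang::warn("no candidate passes the Ljung-Box whiteness screen; falling back to minimum AIC.")
    ok
  }
  best <- pool[order(tab$aic[pool], tab$bic[pool])][1]
  out <- fits[[best]]
  attr(out, "candidates") <- tab
  out
}

#' Forecast a fitted seasonal ARIMA model
#'
#' Point forecasts and forecast standard errors for the next `horizon`
#' months; under the difference-integrated model family the standard error is
#' non-decreasing in horizon.
#'
#' @param fit A `sarima_fit`.
#' @param horizon Months ahead (default 12).
#' @param level Confidence level for the prediction interval (default 0.95).
#' @return Tibble: `h` (1..horizon), `point`, `se`, `lower`, `upper`, all in
#'   cells/mL (back-transformed when the fit was on logs, in which case the
#'   interval is asymmetric).
#' @export
forecast_sarima <- function(fit, horizon = 12, level = 0.95) {
  stopifnot(inherits(fit, "sarima_fit"), horizon >= 1)
  pr <- stats::predict(fit$model, n.ahead = horizon)
  z <- stats::qnorm(1 - (1 - level) / 2)
  point <- as.numeric(pr$pred)
  se <- as.numeric(pr$se)
  lower <- point - z * se
  upper <- point + z * se
  if (fit$log) {
    point <- exp(point); lower <- exp(lower); upper <- exp(upper)
  }
  tibble::tibble(h = seq_len(horizon), point = point, se = se,
                 lower = lower, upper = upper)
}

#' Periodogram of a class series
#'
#' Raw periodogram used to screen for seasonality before model
#' specification; reported for inspection, never used as an automated gate.
#'
#' @param series Series as in [fit_sarima()].
#' @param detrend Remove a linear trend first (default `TRUE`).
#' @return Tibble: `frequency` (cycles/month), `period` (months), `spec`.
#' @export
series_periodogram <- function(series, detrend = TRUE) {
  x <- series_values(series)
  pg <- stats::spec.pgram(stats::ts(x, frequency = 1), detrend = detrend,
                          taper = 0, plot = FALSE)
  tibble::tibble(frequency = pg$freq, period = 1 / pg$freq,
                 spec = pg$spec)
}

#' Reference 12-month class-level BTSCC forecasts
#'
#' The published 12-month-ahead forecasts (point +/- standard error, in
#' thousands of cells/mL, here returned in cells/mL) for the five payment
#' classes for the months of 2016, produced by the per-class seasonal ARIMA
#' models of [reference_sarima_specs()] on the proprietary 1,013-farm series.
#' These printed values are the input to the loss table in
#' [monthly_loss_table()].
#'
#' @return Tibble: `class_index`, `month` (1-12), `year` (2016), `point`,
#'   `se` (cells/mL).
#' @export
reference_forecasts <- function() {
  point <- c(
    206, 210, 208, 210, 195, 194, 204, 197, 196, 206, 214, 222,
    366, 382, 372, 366, 350, 355, 349, 347, 336, 357, 382, 401,
    589, 609, 582, 582, 546, 544, 530, 527, 511, 552, 593, 594,
    753, 783, 738, 765, 704, 725, 727, 710, 701, 737, 788, 814,
    1196, 1218, 1224, 1227, 1156, 1149, 1108, 1069, 1032, 1122, 1205, 1202
  )
  se <- c(
    9, 11, 11, 12, 14, 14, 15, 16, 17, 18, 18, 19,
    14, 16, 18, 20, 22, 24, 26, 27, 28, 30, 31, 32,
    21, 24, 28, 31, 34, 37, 40, 42, 45, 47, 49, 51,
    27, 30, 33, 36, 39, 41, 43, 46, 48, 50, 52, 54,
    58, 64, 76, 83, 91, 98, 105, 111, 117, 123, 128, 133
  )
  tibble::tibble(
    class_index = rep(1:5, each = 12),
    year = 2016L,
    month = rep(1:12, times = 5),
    point = point * 1000,
    se = se * 1000
  )
}

#' Read a two-column monthly series
#'
#' @param path CSV with columns `year`, `month`, `value`.
#' @return Tibble sorted by month.
#' @export
read_series <- function(path) {
  s <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("year", "month", "value") %in% names(s)))
  dplyr::arrange(s, month_index(.data$year, .data$month))
}

#' Write a forecast table in the reference layout
#'
#' One row per month, one `point +/- se` pair of columns per class.
#'
#' @param forecasts Long forecast tibble (`class_index`, `month`, `point`,
#'   `se`).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_forecast_table <- function(forecasts, path) {
  wide <- forecasts |>
    tidyr::pivot_wider(
      id_cols = dplyr::any_of(c("year", "month")),
      names_from = "class_index",
      values_from = c("point", "se"),
      names_glue = "{.value}_class{class_index}"
    )
  readr::write_csv(wide, path)
  invisible(path)
}
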