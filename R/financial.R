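# Milk-equivalent financial losses from forecast BTSCC.

#' Financial parameters of a farm
#'
#' @param daily_production Liters of milk per day (DP); > 0.
#' @param profit_margin Profit margin as a fraction (PM); default 0.15.
#' @param milk_price Currency per liter (MP); default 1.34, the reference
#'   price at which 1 liter equals 1 milk-equivalent.
#' @return A list of class `financial_params`.
#' @examples
#' financial_params(3750)
#' @export
financial_params <- function(daily_production, profit_margin = 0.15,
                             milk_price = 1.34) {
  stopifnot(daily_production > 0, profit_margin > 0, profit_margin < 1,
            milk_price > 0)
  structure(
    list(daily_production = daily_production, profit_margin = profit_margin,
         milk_price = milk_price),
    class = "financial_params"
  )
}

#' Monthly and annual milk-equivalent losses per class from forecasts
#'
#' Each forecast BTSCC point is classified with [assign_class()]; the monthly
#' loss is the per-liter milk-equivalent difference between the forecast
#' month's class and the best class ([loss_vs_best()]). The annual average is
#' the mean of the 12 monthly losses, rounded to 3 decimals — the AFLC
#' (average financial loss of the class) used by [liters_per_day_pct()] and
#' [farm_scenario()]. Applied to the published forecasts
#' ([reference_forecasts()]) this regenerates the published loss table.
#'
#' @param forecasts Long tibble with `class_index`, `month`, `point`
#'   (cells/mL); 12 months per class.
#' @param scheme A `sccpay_scheme`.
#' @return List of class `loss_table`: `monthly` (tibble `class_index`,
#'   `month`, `forecast_class`, `loss` in milk-equivalents/liter) and
#'   `annual` (tibble `class_index`, `annual_loss` rounded to 3 decimals).
#' @examples
#' loss_table(reference_forecasts())
#' @export
monthly_loss_table <- function(forecasts, scheme = payment_scheme()) {
  stopifnot(all(c("class_index", "month", "point") %in% names(forecasts)))
  counts <- dplyr::count(forecasts, .data$class_index)
  if (any(counts$n != 12)) {
    abort_bad_input("each class needs exactly 12 monthly forecast points.")
  }
  monthly <- forecasts |>
    dplyr::mutate(
      forecast_class = assign_class(.data$point, scheme),
      loss = loss_vs_best(.data$forecast_class, scheme)
    ) |>
    dplyr::select(dplyr::any_of(c("class_index", "year", "month")),
                  "point", "forecast_class", "loss")
  annual <- monthly |>
    dplyr::group_by(.data$class_index) |>
    dplyr::summarise(annual_loss = round(mean(.data$loss), 3),
                     .groups = "drop")
  structure(list(monthly = monthly, annual = annual), class = "loss_table")
}

#' @rdname monthly_loss_table
#' @export
loss_table <- monthly_loss_table

#' @export
print.loss_table <- function(x, ...) {
  cat("Monthly milk-equivalent losses per liter by class\n")
  wide <- tidyr::pivot_wider(
    x$monthly,
    id_cols = dplyr::any_of(c("year", "month")),
    names_from = "class_index", values_from = "loss",
    names_prefix = "class_"
  )
  print(wide, n = 12)
  cat("Annual averages:\n")
  print(x$annual)
  invisible(x)
}

#' Write a loss table (classes as columns, months as rows, annual footer)
#'
#' @param x A `loss_table`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_loss_table <- function(x, path) {
  wide <- tidyr::pivot_wider(
    x$monthly,
    id_cols = dplyr::any_of(c("year", "month")),
    names_from = "class_index", values_from = "loss",
    names_prefix = "class_"
  )
  footer <- tidyr::pivot_wider(
    x$annual, names_from = "class_index", values_from = "annual_loss",
    names_prefix = "class_"
  )
  for (nm in setdiff(names(wide), names(footer))) {
    footer[[nm]] <- if (nm == "month") NA_integer_ else NA
  }
  readr::write_csv(dplyr::bind_rows(wide, footer[names(wide)]), path)
  invisible(path)
}

#' Daily production percentage equivalent to a class's financial loss
#'
#' The share of a farm's daily production whose profit the payment scheme
#' loss consumes: `(DP * |AFLC|) / (PM * MP) / DP`, which reduces to
#' `|AFLC| / PM` when the loss is quoted in milk-equivalents — independent of
#' both the production level and the milk price. Reported truncated to one
#' decimal.
#'
#' @param aflc Average financial loss of the class, milk-equivalents per
#'   liter (<= 0; the magnitude is used).
#' @param profit_margin Profit margin fraction (default 0.15).
#' @param display Truncate to one decimal (default `TRUE`, the reporting
#'   convention); set `FALSE` for full precision.
#' @return Percent of daily production.
#' @examples
#' liters_per_day_pct(c(-0.010, -0.016, -0.037, -0.038, -0.045))
#' # 6.6 10.6 24.6 25.3 30.0
#' @export
liters_per_day_pct <- function(aflc, profit_margin = 0.15, display = TRUE) {
  stopifnot(all(is.finite(aflc)), all(aflc <= 0), profit_margin > 0)
  pct <- 100 * abs(aflc) / profit_margin
  if (display) trunc_to(pct, 1) else pct
}

#' Full decision report for one farm
#'
#' Chains the whole analysis for a single farm given two consecutive monthly
#' BTSCC means: moving-range SD, payment class, probability of dropping to a
#' worse class next month, and the financial consequences of the class's
#' average annual loss — the extra liters per day needed to offset it
#' (`DP * |AFLC| / PM`), the monthly loss in milk-equivalents (extra liters
#' x 30 days) and currency, the additional cows required at the herd's
#' per-cow yield, and the loss as a share of daily production.
#'
#' @param current_mean,prev_mean Monthly geometric mean BTSCC (cells/mL) for
#'   the current and immediately preceding calendar month.
#' @param herd_size Lactating cows.
#' @param per_cow Liters per cow per day.
#' @param losses A `loss_table` (default: regenerated from
#'   [reference_forecasts()]).
#' @param params A [financial_params()]; defaults to
#'   `herd_size * per_cow` liters/day at the default margin and price.
#' @param model Class-change model passed to
#'   [predict_change_probability()] (default: published equations).
#' @param scheme A `sccpay_scheme`.
#' @return One-row tibble: `est_sd` (truncated to cells/mL), `class_index`,
#'   `change_probability` (whole percent), `aflc`, `extra_liters_day`,
#'   `monthly_milk_equiv`, `monthly_currency`, `extra_cows_exact`,
#'   `extra_cows` (ceiling), `pct_production` (truncated to one decimal).
#' @examples
#' farm_scenario(350000, 315000, herd_size = 150, per_cow = 25)
#' @export
farm_scenario <- function(current_mean, prev_mean, herd_size, per_cow,
                          losses = monthly_loss_table(reference_forecasts()),
                          params = NULL, model = NULL,
                          scheme = payment_scheme()) {
  stopifnot(herd_size > 0, per_cow > 0)
  if (is.null(params)) {
    params <- financial_params(herd_size * per_cow,
                               milk_price = milk_price(scheme))
  }
  dp <- params$daily_production
  est_sd <- moving_range_sd(prev_mean, current_mean)
  cls <- assign_class(current_mean, scheme)
  prob <- if (cls <= 4) {
    predict_change_probability(current_mean, est_sd, model, scheme)
  } else {
    NA_real_
  }
  aflc <- losses$annual$annual_loss[losses$annual$class_index == cls]
  if (length(aflc) != 1) {
    abort_bad_input(sprintf("loss table has no annual average for class %d.", cls))
  }
  extra <- dp * abs(aflc) / params$profit_margin
  monthly_me <- extra * 30
  tibble::tibble(
    current_mean = current_mean,
    prev_mean = prev_mean,
    est_sd = trunc_to(est_sd),
    class_index = cls,
    change_probability = round(prob),
    aflc = aflc,
    extra_liters_day = extra,
    monthly_milk_equiv = monthly_me,
    monthly_currency = monthly_me * params$milk_price,
    extra_cows_exact = extra / per_cow,
    extra_cows = ceiling(extra / per_cow),
    pct_production = trunc_to(100 * extra / dp, 1)
  )
}
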