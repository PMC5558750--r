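# Monthly aggregation and moving-range variation estimation.

#' SPC constant d2 for moving ranges of individuals (n = 2)
#'
#' Tabulated statistical-process-control constant relating the mean moving
#' range of an individuals series to its standard deviation.
#' @export
d2_constant <- 1.128

#' Geometric mean
#'
#' The standard BTSCC aggregation: `exp(mean(log(values)))`. Used both within
#' a farm-month (3-5 bulk-tank samples) and across farms within a month.
#'
#' @param values Positive numeric vector, cells/mL.
#' @param na_rm Drop `NA`s before averaging.
#' @return Scalar geometric mean.
#' @examples
#' geometric_mean(c(100, 10000))  # 1000
#' @export
geometric_mean <- function(values, na_rm = FALSE) {
  if (na_rm) values <- values[!is.na(values)]
  check_positive_finite(values, "values")
  exp(mean(log(values)))
}

#' Moving-range estimate of between-month BTSCC standard deviation
#'
#' The between-month variation of a farm's BTSCC is estimated from two
#' consecutive monthly geometric means as `|curr - prev| / d2` with
#' d2 = 1.128, the individuals-chart moving-range estimator. For the
#' reporting convention (truncation to integer cells/mL) see [trunc_to()];
#' this function returns full precision.
#'
#' @param prev_mean,curr_mean Monthly geometric means (cells/mL) of two
#'   consecutive calendar months, both positive.
#' @return Estimated standard deviation, cells/mL.
#' @examples
#' moving_range_sd(250000, 220000)        # 26595.74...
#' trunc_to(moving_range_sd(315000, 350000))  # 31028
#' @export
moving_range_sd <- function(prev_mean, curr_mean) {
  check_positive_finite(prev_mean, "prev_mean")
  check_positive_finite(curr_mean, "curr_mean")
  abs(curr_mean - prev_mean) / d2_constant
}

#' Read a farm-month BTSCC panel
#'
#' Expects columns `farm_id`, `year`, `month` and either sample columns
#' `scc_1`..`scc_5` (blank-padded) or a pre-computed `geo_mean` column.
#'
#' @param path CSV path.
#' @return A tibble, one row per farm-month.
#' @export
read_panel <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write a farm-month panel
#' @param panel Panel tibble.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(panel, path)
  invisible(path)
}

#' Enrich a farm-month panel with geometric means, moving-range SDs and classes
#'
#' For each farm-month: computes the geometric mean over the available
#' within-month samples (columns `scc_1`..`scc_5`) unless a `geo_mean` column
#' is already present; estimates the between-month standard deviation by the
#' moving-range method whenever the immediately preceding calendar month has a
#' record for the same farm (otherwise `est_sd` is `NA`); and assigns the
#' payment class of the month's geometric mean.
#'
#' @param panel Tibble with `farm_id`, `year`, `month` and sample columns or
#'   `geo_mean`.
#' @param scheme A `sccpay_scheme`.
#' @param min_samples Warn when a farm-month has fewer within-month samples
#'   than this (default 3, matching the usual 3-5 sampling design).
#' @return The panel with `geo_mean`, `est_sd`, `class_index` columns, sorted
#'   by farm and month.
#' @export
enrich_panel <- function(panel, scheme = payment_scheme(), min_samples = 3) {
  stopifnot(all(c("farm_id", "year", "month") %in% names(panel)))
  panel <- tibble::as_tibble(panel)
  if (!"geo_mean" %in% names(panel)) {
    scc_cols <- grep("^scc_[0-9]+$", names(panel), value = TRUE)
    if (length(scc_cols) == 0) {
      abort_bad_input("panel needs `geo_mean` or `scc_1`..`scc_5` columns.")
    }
    mat <- as.matrix(panel[scc_cols])
    n_samp <- rowSums(!is.na(mat))
    if (any(n_samp == 0)) {
      abort_bad_input("some farm-months have no SCC samples at all.")
    }
    if (any(n_samp < min_samples)) {
      rlang::warn(sprintf(
        "%d farm-month(s) have fewer than %d within-month samples.",
        sum(n_samp < min_samples), min_samples
      ))
    }
    panel$geo_mean <- exp(rowMeans(log(mat), na.rm = TRUE))
  }
  check_positive_finite(panel$geo_mean, "geo_mean")

  panel |>
    dplyr::mutate(.midx = month_index(.data$year, .data$month)) |>
    dplyr::arrange(.data$farm_id, .data$.midx) |>
    dplyr::group_by(.data$farm_id) |>
    dplyr::mutate(
      est_sd = dplyr::if_else(
        .data$.midx - dplyr::lag(.data$.midx) == 1L,
        abs(.data$geo_mean - dplyr::lag(.data$geo_mean)) / d2_constant,
        NA_real_
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(class_index = assign_class(.data$geo_mean, scheme)) |>
    dplyr::select(-".midx")
}

#' Period summary of a farm-month panel
#'
#' Aggregates a panel to one cross-farm geometric mean per month, then reports
#' the arithmetic mean, geometric mean and median of those monthly values,
#' together with the mean monthly farm count and its normal-approximation 95%
#' confidence interval (mean +/- 1.96 SE across months).
#'
#' @param panel Panel with `geo_mean` (run [enrich_panel()] first if needed).
#' @return One-row tibble: `arith_mean`, `geo_mean`, `median`,
#'   `mean_farms`, `farms_ci_lower`, `farms_ci_upper`, `n_months`.
#' @export
summarize_period <- function(panel) {
  stopifnot(nrow(panel) > 0, "geo_mean" %in% names(panel))
  monthly <- panel |>
    dplyr::group_by(.data$year, .data$month) |>
    dplyr::summarise(
      value = geometric_mean(.data$geo_mean),
      n_farms = dplyr::n(),
      .groups = "drop"
    )
  n <- nrow(monthly)
  se <- stats::sd(monthly$n_farms) / sqrt(n)
  if (n == 1) se <- 0
  tibble::tibble(
    arith_mean = mean(monthly$value),
    geo_mean = geometric_mean(monthly$value),
    median = stats::median(monthly$value),
    mean_farms = mean(monthly$n_farms),
    farms_ci_lower = mean(monthly$n_farms) - 1.96 * se,
    farms_ci_upper = mean(monthly$n_farms) + 1.96 * se,
    n_months = n
  )
}
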