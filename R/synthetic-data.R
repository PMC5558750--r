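# Synthetic farm-month BTSCC panels with the statistical structure the
# analysis assumes: lognormal cross-farm spread, 12-month seasonality,
# AR(1) month-to-month autocorrelation in log space, and a mild yearly trend.

#' Configuration of the synthetic panel generator
#'
#' The generator works in log space: for farm i in month t,
#' `log SCC = farm_effect_i + trend * (t-1)/12 +
#'  seasonal_amplitude * cos(2*pi*(month - peak_month)/12) + AR(1) noise`,
#' with farm effects drawn lognormally across farms and 3-5 within-month
#' samples scattered around the month value with coefficient of variation
#' `within_month_cv`. Defaults emulate a Brazilian-style panel: median farm
#' around 380,000 cells/mL with a cross-farm log-SD of 0.6 (spanning all five
#' payment classes), seasonal peak in December (southern-hemisphere summer),
#' moderate month-to-month persistence, and a mild upward yearly drift.
#'
#' @param n_farms Number of farms.
#' @param n_months Panel length in months (default 60, a 5-year design).
#' @param start_year,start_month First calendar month (default Jan 2011).
#' @param samples_per_month Integer range of within-month samples, default
#'   `c(3, 5)`.
#' @param farm_median Median farm-level BTSCC, cells/mL (default 380,000).
#' @param farm_sdlog Cross-farm SD of log BTSCC (default 0.6).
#' @param seasonal_amplitude Amplitude of the seasonal cosine on the log
#'   scale (default 0.08, i.e. about +/-8% seasonal swing).
#' @param peak_month Calendar month of the seasonal high (default 12,
#'   December — the hot season).
#' @param ar_coefficient AR(1) coefficient of the monthly log deviations,
#'   |value| < 1 (default 0.5).
#' @param ar_sd Innovation SD of the AR(1) process on the log scale
#'   (default 0.10).
#' @param trend Multiplicative drift per year on the log scale
#'   (default 0.02).
#' @param within_month_cv Coefficient of variation of within-month samples
#'   around the month value (default 0.15).
#' @param missing_rate Probability that a farm-month record is absent
#'   (default 0).
#' @param seed Integer seed; identical seeds give identical panels, and each
#'   farm has a deterministic sub-stream so farm subsets are reproducible.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_farms = 100, n_months = 60,
                             start_year = 2011, start_month = 1,
                             samples_per_month = c(3, 5),
                             farm_median = 380000, farm_sdlog = 0.6,
                             seasonal_amplitude = 0.08, peak_month = 12,
                             ar_coefficient = 0.5, ar_sd = 0.10,
                             trend = 0.02, within_month_cv = 0.15,
                             missing_rate = 0, seed = 1) {
  cfg <- list(
    n_farms = as.integer(n_farms), n_months = as.integer(n_months),
    start_year = as.integer(start_year), start_month = as.integer(start_month),
    samples_per_month = as.integer(samples_per_month),
    farm_median = farm_median, farm_sdlog = farm_sdlog,
    seasonal_amplitude = seasonal_amplitude, peak_month = as.integer(peak_month),
    ar_coefficient = ar_coefficient, ar_sd = ar_sd,
    trend = trend, within_month_cv = within_month_cv,
    missing_rate = missing_rate, seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_farms >= 0, cfg$n_months >= 1,
    cfg$start_month %in% 1:12, cfg$peak_month %in% 1:12,
    length(cfg$samples_per_month) == 2,
    cfg$samples_per_month[1] >= 1,
    cfg$samples_per_month[1] <= cfg$samples_per_month[2],
    cfg$farm_median > 0, cfg$farm_sdlog >= 0,
    cfg$seasonal_amplitude >= 0, abs(cfg$ar_coefficient) < 1,
    cfg$ar_sd >= 0, cfg$within_month_cv >= 0,
    cfg$missing_rate >= 0, cfg$missing_rate < 1
  )
  structure(cfg, class = "synthetic_config")
}

farm_substream_seed <- function(seed, farm, salt = 0L) {
  # deterministic 31-bit per-farm seed so farm subsets are reproducible
  (abs(seed) %% 100000L) * 20011L + farm * 127L + salt * 7919L
}

# One farm's records. `farm_effect` may be supplied (class-balanced
# generation); otherwise it is drawn from the farm-level lognormal inside the
# farm's own sub-stream.
generate_farm <- function(cfg, farm, farm_effect = NULL, salt = 0L) {
  set.seed(farm_substream_seed(cfg$seed, farm, salt))
  if (is.null(farm_effect)) {
    farm_effect <- stats::rnorm(1, log(cfg$farm_median), cfg$farm_sdlog)
  }
  n <- cfg$n_months
  t <- seq_len(n)
  midx <- month_index(cfg$start_year, cfg$start_month) + t - 1L
  ym <- month_index_to_ym(midx)
  season <- cfg$seasonal_amplitude *
    cos(2 * pi * (ym$month - cfg$peak_month) / 12)
  drift <- cfg$trend * (t - 1) / 12
  e <- if (cfg$ar_sd > 0) {
    as.numeric(stats::arima.sim(
      list(ar = if (cfg$ar_coefficient != 0) cfg$ar_coefficient else NULL),
      n = n, sd = cfg$ar_sd
    ))
  } else {
    numeric(n)
  }
  log_month <- farm_effect + drift + season + e

  samp_range <- seq(cfg$samples_per_month[1], cfg$samples_per_month[2])
  n_samp <- if (length(samp_range) == 1) {
    rep(samp_range, n)
  } else {
    sample(samp_range, n, replace = TRUE)
  }
  sdlog_within <- sqrt(log(1 + cfg$within_month_cv^2))
  max_s <- cfg$samples_per_month[2]
  scc <- matrix(NA_real_, n, max_s,
                dimnames = list(NULL, paste0("scc_", seq_len(max_s))))
  for (i in t) {
    scc[i, seq_len(n_samp[i])] <-
      exp(stats::rnorm(n_samp[i], log_month[i], sdlog_within))
  }
  keep <- stats::runif(n) >= cfg$missing_rate
  out <- tibble::tibble(
    farm_id = sprintf("farm_%04d", farm),
    year = ym$year, month = ym$month
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(scc))
  out[keep, , drop = FALSE]
}

#' Generate a synthetic farm-month BTSCC panel
#'
#' @param config A [synthetic_config()].
#' @return Tibble with `farm_id`, `year`, `month` and sample columns
#'   `scc_1`..`scc_k` (NA-padded to the maximum samples per month), ready for
#'   [enrich_panel()]. Deterministic under the config's seed.
#' @examples
#' panel <- generate_panel(synthetic_config(n_farms = 3, n_months = 6))
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_farms == 0) return(empty_panel(config))
  purrr::map(seq_len(config$n_farms), \(i) generate_farm(config, i)) |>
    purrr::list_rbind()
}

empty_panel <- function(config) {
  cols <- c("farm_id", "year", "month",
            paste0("scc_", seq_len(config$samples_per_month[2])))
  out <- tibble::tibble(farm_id = character(), year = integer(),
                        month = integer())
  for (nm in setdiff(cols, names(out))) out[[nm]] <- double()
  out
}

#' Generate a panel with a requested number of farms per payment class
#'
#' Farm-level medians are drawn inside each requested class's BTSCC interval
#' and the resulting farms verified post hoc: a farm whose whole-period
#' geometric mean lands outside the requested class is redrawn (bounded
#' retries), so the classification round-trip
#' ([select_complete_farms()]) returns exactly the requested allocation.
#' Missingness is disabled (complete-record farms are the point).
#'
#' @param per_class_counts Integer vector of length 5: farms wanted in
#'   classes 1-5.
#' @param config A [synthetic_config()]; `n_farms` and `missing_rate` are
#'   overridden.
#' @param scheme A `sccpay_scheme`.
#' @param max_retries Redraw budget per farm (default 50).
#' @return Panel tibble as in [generate_panel()].
#' @export
generate_class_balanced_panel <- function(per_class_counts,
                                          config = synthetic_config(),
                                          scheme = payment_scheme(),
                                          max_retries = 50) {
  stopifnot(length(per_class_counts) == 5, all(per_class_counts >= 0))
  cfg <- config
  cfg$missing_rate <- 0
  if (sum(per_class_counts) == 0) return(empty_panel(cfg))

  lower <- pmax(scheme$lower_kcells * 1000 - 1000, 50000)
  upper <- ifelse(is.finite(scheme$upper_kcells),
                  scheme$upper_kcells * 1000, 2e6)

  farm <- 0L
  out <- vector("list", sum(per_class_counts))
  for (k in 1:5) {
    for (j in seq_len(per_class_counts[k])) {
      farm <- farm + 1L
      ok <- FALSE
      for (attempt in seq_len(max_retries)) {
        set.seed(farm_substream_seed(cfg$seed, farm, salt = attempt))
        # shrink toward the class centre so noise rarely pushes the period
        # mean across a bound
        lo <- log(lower[k]); hi <- log(upper[k])
        f_eff <- stats::runif(1, lo + 0.15 * (hi - lo), hi - 0.15 * (hi - lo))
        rec <- generate_farm(cfg, farm, farm_effect = f_eff, salt = attempt)
        enr <- enrich_panel(rec, scheme)
        period <- geometric_mean(enr$geo_mean)
        if (assign_class(period, scheme) == k) {
          out[[farm]] <- rec
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        rlang::abort(sprintf(
          "could not place a farm in class %d within %d retries; noise level may be infeasible for the class bounds.",
          k, max_retries
        ), class = "sccpay_infeasible_class")
      }
    }
  }
  purrr::list_rbind(out)
}
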