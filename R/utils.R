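# Internal helpers shared across modules.

#' Truncate toward zero to a number of decimal digits
#'
#' Display rule used for reported quantities: the moving-range standard
#' deviation is truncated to integer cells/mL and the production percentages
#' to one decimal. Full precision is always retained internally; this helper
#' is applied only at the reporting boundary.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep (default 0).
#' @return Numeric vector truncated toward zero.
#' @examples
#' trunc_to(31028.37)       # 31028
#' trunc_to(10.666, 1)      # 10.6
#' trunc_to(-25.333, 1)     # -25.3
#' @export
trunc_to <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1, digits >= 0)
  f <- 10^digits
  trunc(x * f) / f
}

# Encode calendar (year, month) as a single integer month index so that
# consecutive calendar months differ by exactly 1 (Dec -> Jan included).
month_index <- function(year, month) {
  stopifnot(all(month %in% 1:12))
  as.integer(year) * 12L + (as.integer(month) - 1L)
}

month_index_to_ym <- function(idx) {
  tibble::tibble(year = idx %/% 12L, month = idx %% 12L + 1L)
}

abort_bad_input <- function(msg) {
  rlang::abort(msg, class = "sccpay_invalid_input")
}

check_positive_finite <- function(x, what) {
  if (length(x) == 0 || anyNA(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort_bad_input(sprintf("`%s` must be positive and finite.", what))
  }
  invisible(x)
}
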