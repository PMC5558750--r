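#' Reference milk-quality payment scheme
#'
#' Builds the PPBMQ (payment program based on milk quality) reference table:
#' five BTSCC classes with their per-liter bonus/penalty in currency (R$) and
#' in milk-equivalents (liters of milk at the reference price). The default
#' reproduces the reference table aggregated from the payment tables of 13
#' Brazilian milk buyers: classes 1-200, 201-400, 401-500, 501-800 and > 800
#' thousand cells/mL paying +0.030, +0.015, 0.000, -0.007 and -0.015
#' milk-equivalents per liter.
#'
#' Class bounds are labelled in thousands of cells/mL with touching labels
#' (1-200, 201-400, ...): class k covers the upper-inclusive interval
#' `(lower - 1, upper] * 1000` on cells/mL, so 200,000 cells/mL is class 1 and
#' 200,001 is class 2. Values below 1,000 cells/mL are legitimate best-quality
#' milk and fall in class 1.
#'
#' @param milk_price Reference milk price in currency per liter; 1 liter of
#'   milk-equivalent is worth `milk_price`. Default 1.34 (R$/L).
#' @return A tibble with class `sccpay_scheme`, one row per payment class:
#'   `class_index`, `lower_kcells`, `upper_kcells` (`Inf` for the open top
#'   class), `bonus_currency`, `bonus_milk_equiv`, plus a `milk_price`
#'   attribute.
#' @examples
#' payment_scheme()
#' @export
payment_scheme <- function(milk_price = 1.34) {
  scheme <- tibble::tibble(
    class_index = 1:5,
    lower_kcells = c(1, 201, 401, 501, 801),
    upper_kcells = c(200, 400, 500, 800, Inf),
    bonus_currency = c(0.040, 0.020, 0.000, -0.010, -0.020),
    bonus_milk_equiv = c(0.030, 0.015, 0.000, -0.007, -0.015)
  )
  new_scheme(scheme, milk_price)
}

new_scheme <- function(scheme, milk_price) {
  stopifnot(milk_price > 0)
  scheme <- tibble::as_tibble(scheme)
  scheme$class_index <- as.integer(scheme$class_index)
  validate_scheme(scheme)
  attr(scheme, "milk_price") <- milk_price
  class(scheme) <- c("sccpay_scheme", class(scheme))
  scheme
}

validate_scheme <- function(scheme) {
  stopifnot(
    all(c("class_index", "lower_kcells", "upper_kcells",
          "bonus_currency", "bonus_milk_equiv") %in% names(scheme)),
    identical(scheme$class_index, seq_len(nrow(scheme))),
    !is.unsorted(scheme$lower_kcells, strictly = TRUE),
    all(scheme$lower_kcells <= scheme$upper_kcells),
    sum(is.infinite(scheme$upper_kcells)) == 1,
    is.infinite(scheme$upper_kcells[nrow(scheme)]),
    # contiguous touching labels in kcells
    all(scheme$lower_kcells[-1] == utils::head(scheme$upper_kcells, -1) + 1),
    !is.unsorted(rev(scheme$bonus_milk_equiv))
  )
  invisible(scheme)
}

#' Read a payment scheme from a delimited file
#'
#' Columns: `class_index`, `lower_kcells`, `upper_kcells` (blank for the
#' unbounded top class), `bonus_currency`, `bonus_milk_equiv`. Buyer-specific
#' tables can be supplied this way; the packaged default is [payment_scheme()].
#'
#' @param path Path to a CSV file.
#' @param milk_price Currency per liter (default 1.34).
#' @return A `sccpay_scheme` tibble.
#' @export
read_payment_scheme <- function(path, milk_price = 1.34) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  raw$upper_kcells <- ifelse(is.na(raw$upper_kcells), Inf, raw$upper_kcells)
  new_scheme(raw[order(raw$class_index), , drop = FALSE], milk_price)
}

#' Milk price attached to a scheme
#' @param scheme A `sccpay_scheme`.
#' @return Currency per liter.
#' @export
milk_price <- function(scheme) {
  attr(scheme, "milk_price")
}

#' Assign BTSCC values to payment classes
#'
#' Maps monthly geometric-mean BTSCC values (cells/mL) to the payment class
#' whose interval contains them. Intervals are upper-inclusive on cells/mL:
#' class 1 is (0, 200,000], class 2 is (200,000, 400,000], and so on, with the
#' top class unbounded. Vectorised and monotone in `btscc`.
#'
#' @param btscc Numeric vector of BTSCC values, cells/mL; must be positive
#'   and finite.
#' @param scheme A `sccpay_scheme`; default [payment_scheme()].
#' @return Integer vector of class indices.
#' @examples
#' assign_class(c(140000, 350000, 850000))  # 1, 2, 5
#' @export
assign_class <- function(btscc, scheme = payment_scheme()) {
  check_positive_finite(btscc, "btscc")
  uppers <- scheme$upper_kcells * 1000
  finite_uppers <- uppers[is.finite(uppers)]
  findInterval(btscc, finite_uppers, left.open = TRUE) + 1L
}

#' Per-liter loss relative to the best payment class
#'
#' The financial loss of sitting in a class is the difference between its
#' milk-equivalent bonus and the best class's bonus; class 1 loses nothing,
#' class 5 loses 0.045 milk-equivalents per liter under the default table.
#'
#' @param class_index Integer vector of class indices.
#' @param scheme A `sccpay_scheme`.
#' @return Numeric vector of milk-equivalents per liter (<= 0).
#' @examples
#' loss_vs_best(1:5)
#' @export
loss_vs_best <- function(class_index, scheme = payment_scheme()) {
  if (anyNA(class_index) || !all(class_index %in% scheme$class_index)) {
    abort_bad_input("`class_index` contains unknown payment classes.")
  }
  scheme$bonus_milk_equiv[class_index] - scheme$bonus_milk_equiv[1]
}

#' Convert milk-equivalents to currency
#'
#' @param milk_equiv Numeric vector, liters of milk-equivalent.
#' @param scheme A `sccpay_scheme` carrying the milk price.
#' @return Currency values (`milk_equiv * milk_price`).
#' @examples
#' to_currency(12000)  # 16080
#' @export
to_currency <- function(milk_equiv, scheme = payment_scheme()) {
  stopifnot(is.numeric(milk_equiv), all(is.finite(milk_equiv)))
  milk_equiv * milk_price(scheme)
}
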