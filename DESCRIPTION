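Package: sccpay
Title: Bulk-Tank Somatic Cell Count Variation, Forecasting and Milk-Quality Payment Losses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing bulk-tank somatic cell count (BTSCC) under
    payment programs based on milk quality (PPBMQ). Estimates between-month
    BTSCC variation with the moving-range/d2 method of statistical process
    control, computes empirical probabilities that a farm drops to a worse
    payment class and fits the quadrant regression behind them, forecasts
    class-level BTSCC with seasonal ARIMA models, and converts forecasts into
    milk-equivalent financial losses, including a per-farm scenario
    calculator. A synthetic farm-panel generator with lognormal cross-farm
    spread, 12-month seasonality, AR(1) month-to-month autocorrelation and a
    yearly trend makes the whole pipeline testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
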