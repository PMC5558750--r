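---
title: "BTSCC variation, class-change risk and payment losses: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BTSCC variation, class-change risk and payment losses: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sccpay)
```

`sccpay` analyses bulk-tank somatic cell count (BTSCC) panels under a
payment program based on milk quality (PPBMQ). This vignette is the
package's account of the statistical machinery: the models, their
assumptions, the tunable parameters, and the numerical conventions. It
states no empirical result beyond what the test suite and the acceptance
script themselves compute.

## The payment scheme

The reference scheme (`payment_scheme()`) has five BTSCC classes with
per-liter bonuses of +0.030, +0.015, 0.000, −0.007 and −0.015
milk-equivalents (a milk-equivalent is one liter of milk at the reference
price, default R$ 1.34/L, so values transfer across currencies). Class
bounds are labelled in thousands of cells/mL with touching labels
(1–200, 201–400, …). We interpret them as upper-inclusive intervals on
cells/mL: class 1 is (0, 200,000], class 2 (200,000, 400,000], and so on.
This matches the 1,000 cells/mL label granularity; 200,000 maps to class 1
and 200,001 to class 2. Geometric means below 1,000 cells/mL — legitimate,
very clean milk — are placed in class 1 even though the printed table
starts at 1,000. Alternative buyer tables load from CSV
(`read_payment_scheme()`); all downstream code takes the scheme as an
argument.

## Between-month variation: the moving range

Within-month standard deviations do not describe how a farm's *monthly*
BTSCC wanders, so the between-month SD is estimated from consecutive
monthly geometric means with the individuals-chart moving-range estimator
of statistical process control, `|x_t − x_{t−1}| / d2`, `d2 = 1.128`.
The estimator needs truly consecutive calendar months; after a reporting
gap no SD is produced for the month following the gap (December→January
across a year boundary does count as consecutive). Farm-months without an
estimated SD are excluded from the class-change denominators — the source
analysis does not state how it handled them, and exclusion is the choice
that leaves every retained observation fully defined.

Reported SDs are truncated toward zero to integer cells/mL (35,000/1.128 =
31,028.37 is reported as 31,028); full precision is kept internally and the
truncation applied only at the reporting boundary (`trunc_to()`).

## Probability of dropping to a worse class

Classes 1–4 (nothing is worse than class 5) are each cut into quadrants:
the mean axis in 50,000 cells/mL steps across the class range (4, 4, 2, 6
bins), the SD axis into ≤50k, 50–100k, 100–150k, 150–200k and >200k —
20, 20, 10 and 30 quadrants. All bins are upper-inclusive, consistent with
the class-bound convention. Per quadrant we record the proportion of
farm-months whose next-month class was strictly worse (any magnitude of
jump counts the same), plus the medians of the contributing means and SDs.
A farm contributes one observation per eligible month; repeated measures
from the same farm are deliberately *not* modelled with a farm random
effect — panels of this kind are heavily unbalanced, and the plain
proportion-by-quadrant design mirrors how the published equations were
estimated.

The regression (`fit_change_model()`) is ordinary least squares of the
quadrant probability on the two medians. For classes 2–4 the response is
log10-transformed — the transform the published equations use — and
predictions back-transform as powers of 10; class 1 is untransformed.
Consequences of the transform: quadrants with probability exactly 0 cannot
enter a log fit and are dropped with a warning and a reported count
(`n_dropped_zero`); a minimum per-quadrant observation count is
configurable (`min_n`, default 1 — no floor is imposed by default).
Assumption checking is graphical by design: `change_model_diagnostics()` /
`plot_change_model_diagnostics()` expose standardized residuals against
fitted values and normal quantiles rather than automated pass/fail tests,
and multicollinearity is summarised by variance inflation factors (values
near 1 uncorrelated, 5–10 concerning). Predictions are clamped to
[0, 100]% and conventionally reported to the whole percent.

The published coefficient sets for classes 1–4 ship as
`published_equations()` and are the default for
`predict_change_probability()`. Their printed intercepts for classes 2–4
are on the log10 scale; the package confirms this reading against the
worked example (mean 350,000, SD 31,028 → 10^1.4846 ≈ 30.5 → 31%) in the
acceptance suite.

## Class-level forecasting

Farms observed in *every* month of the study window (60 months in the
5-year design) are assigned to a class by their whole-period geometric
mean, and each class's series is the per-month cross-farm geometric mean.
Series must be contiguous; `build_class_series()` refuses gaps.

Each series is modelled as a multiplicative seasonal ARIMA,
SARIMA(p,d,q)(P,D,Q)12, fit by maximum likelihood via `stats::arima`. The
five published per-class orders are available as
`reference_sarima_specs()`; `select_spec()` picks among candidates by
minimum AIC with BIC tie-break, restricted to fits whose residuals pass a
Ljung-Box whiteness screen at p > 0.05 when any do (with a warned fallback
to minimum AIC otherwise). Numerical conventions:

* **Ljung-Box lag**: not stated in the source; default `min(24, n/5)`,
  raised when necessary so the degrees of freedom stay positive after
  subtracting the `p+q+P+Q` fitted parameters. Configurable via `lb_lag`.
* **Scale**: raw cells/mL by default (published forecast errors are
  symmetric on the count scale); `log = TRUE` fits on logs and
  back-transforms, giving asymmetric intervals.
* **Reproducibility**: `stats::arima`'s ML optimisation is deterministic
  given the data and order, so refits reproduce forecasts bit-for-bit.
* A periodogram (`series_periodogram()`) is reported for seasonality
  screening but never used as an automated gate.

Forecasts (`forecast_sarima()`) return point, standard error and normal
prediction intervals per horizon; under the difference-integrated family
the standard error is non-decreasing in horizon.

## Financial losses

`monthly_loss_table()` classifies each forecast month's point value and
takes the milk-equivalent difference to the best class; the annual average
(the class AFLC) is the mean of the 12 monthly losses rounded to 3
decimals *before* downstream use. `liters_per_day_pct()` implements
`(DP·|AFLC|)/(PM·MP)/DP`, which reduces to |AFLC|/PM when the loss is in
milk-equivalents — independent of both production level and milk price —
and is reported truncated (not rounded) to one decimal, the convention the
printed percentages imply (0.016/0.15 = 10.66… → 10.6; 0.038/0.15 =
25.33… → 25.3). The farm scenario's monthly loss is *extra liters × 30
days* (a month is fixed at 30 days), not per-liter loss × production —
the two differ, and the package follows the published chain. The extra-cow
count divides extra liters by per-cow yield; both the exact quotient and
its ceiling are reported since the convention for non-integer results is
unstated in the source chain (which happened to divide exactly).

## The synthetic generator

Real multi-farm BTSCC databases are proprietary, so `generate_panel()`
produces panels with the structure the analysis assumes, in log space:

* farm effects lognormal across farms (`farm_median` 380,000 cells/mL,
  `farm_sdlog` 0.6 — wide enough to populate all five classes, loosely
  calibrated to the class-level means a national database displays);
* a seasonal cosine (`seasonal_amplitude` 0.08 on the log scale) peaking in
  December (`peak_month` 12, the southern-hemisphere hot season — counts
  rise in hot months);
* AR(1) month-to-month persistence (`ar_coefficient` 0.5, innovation SD
  0.10) and a mild upward drift (`trend` 0.02/year on logs);
* 3–5 within-month samples with coefficient of variation 0.15, and
  optional missingness.

Each farm draws from a deterministic sub-stream keyed by the global seed,
so farm subsets are reproducible. `generate_class_balanced_panel()` draws
farm medians inside requested class intervals (shrunk 15% toward the
centre so period means rarely cross a bound) and verifies the
classification round-trip post hoc with bounded redraws.

What the generator does **not** emulate: mastitis outbreak dynamics and
intervention effects, herd demography, reporting artefacts correlated with
quality, buyer-specific sampling cadences, and cross-farm correlation
beyond the shared seasonal term. Tests passing on synthetic panels
therefore validate the *pipeline arithmetic and estimators*, not claims
about any real population.

## Problem sizes and stochastic tolerances

Simulation-based checks use sizes chosen to keep Monte Carlo error well
inside their tolerances: quadrant-regression recovery on the 20-cell
class-2 grid with noise SD 0.02 (3-SE criterion); SARIMA recovery on
120-month series (2-SE criterion) and 95% interval coverage over 200
simulated series with a ±0.05 band fixed in advance; generator
amplitude/AR recovery on 50–60 farms × 60 months with SE-based bands. The
brute-force quadrant oracle enumerates all consecutive farm-month pairs
directly and must agree exactly.

## Known limitations

* The published class-change equations were estimated on a national
  Brazilian database; applying them to other populations is extrapolation.
* The class-change model treats quadrant proportions as independent
  observations; it ignores overdispersion and within-farm correlation.
* Forecast intervals assume Gaussian innovations on the fitted scale.
* The financial module prices only the PPBMQ differential — no feed,
  treatment or culling costs, and a single configurable milk price.
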