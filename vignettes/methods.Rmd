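---
title: "Quasi-experimental evaluation of a dated global intervention: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-experimental evaluation of a dated global intervention: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itsevent)
```

## The problem

An international treaty aimed at curbing tobacco use is adopted in a known
calendar year (2003 in the motivating application; negotiations began in
1999, and each country became legally bound in its own ratification year).
Did the trajectory of cigarette consumption — measured as cigarettes
consumed per adult aged 15+ per year, observed annually per country —
change when the treaty arrived? There is no control group: essentially
every country is exposed, directly or through market and normative
spillovers. The package therefore implements the two standard
counterfactual designs for a single treated time series:

1. **Interrupted time series (ITS)** on the first-differenced,
   population-weighted aggregate series, where the counterfactual is the
   continuation of the pre-intervention linear trend.
2. **In-sample forecast event modelling**, where the counterfactual is a
   covariate regression fitted on pre-intervention country-years and
   projected forward using post-intervention covariate values.

Both are run globally and within strata (income tier, UN region, OECD
membership), because a null global effect can mask offsetting effects in
subgroups — the package ships a reproducible demonstration of exactly that
masking phenomenon.

## Aggregation and event-time realignment

Group series are adult-population-weighted means of the per-adult outcome,
`sum(y_i * pop_i) / sum(pop_i)`, over the countries observed in each year
(per-year complete cases). The weight base is the adult (15+) population —
the outcome's own denominator — which keeps the aggregate interpretable as
consumption per adult in the group; an unweighted mode is exposed because
the choice of weight base is a genuine degree of freedom in this design.
Weighting is invariant to rescaling all populations, and reduces exactly
to the plain mean under equal populations (both are tested properties).

For legal-effect analyses each country's series can be re-indexed to event
time `year - ratification_year` (`realign_to_event_time()`), so `T0` is
the year the treaty became binding on that country; comparisons then use
the windows `T-3..T-1` against `T+1..T+3`, skipping `T0` itself, which an
optional window argument implements. Countries that never ratified are
excluded and reported.

## First differencing and the stationarity check

Consumption levels are strongly trending and close to unit-root
non-stationary, so the ITS operates on annual changes
`dy_t = y_t - y_{t-1}`. Differences are never taken across gaps in the
time index. Stationarity is checked with the simple Dickey-Fuller test
(zero augmentation lags — the minimal reading of "Dickey-Fuller", with the
variant configurable): regress `dz_t` on `z_{t-1}` plus a constant
(default; optionally no constant, or constant plus trend) and compare the
t-ratio of the lagged level against finite-sample critical values from the
standard published tables, interpolated in `1/n` between tabulated sample
sizes. Results are reported as p-value brackets (`<0.01`, `<0.05`,
`<0.10`, `>=0.10`), the granularity at which such tables are usually
published. On the package's synthetic panels the levels fail to reject and
the differences reject at `P<0.01`, matching the regime the design
assumes. `fit_its()` re-runs the check and warns when the differenced
series does not reject.

## The segmented regression

On the differenced series with cutoff year `c` (2003 primary, 1999
secondary):

$$
\Delta y_t = \beta_0 + \beta_1 (t - t_{first}) + \beta_2 D_t +
\beta_3 (t - c) D_t + \varepsilon_t, \qquad D_t = \mathbf{1}[t \ge c + 1].
$$

Because the outcome is already a rate of change, `beta_2` (level change)
is a one-time acceleration or deceleration of consumption at the cutoff,
and `beta_3` (trend change) is the ongoing change in that rate per year.
Two parameterisation decisions matter and are fixed throughout:

* the post period starts the year **after** the cutoff (a 2003 adoption is
  evaluated "from 2004 onwards"), so the cutoff-year observation is pre;
* the trend-change clock is centred at the cutoff, `(t - c) D_t`, so
  `beta_2` is the discontinuity at the cutoff itself.

Inference uses the t distribution with `n - 4` degrees of freedom.
Classical OLS standard errors are the default; a Newey-West HAC variant
with one lag is exposed because the exact error model behind published
coefficient tables of this kind is rarely recoverable. Each coefficient's
significance tier (none/90/95/99) is the highest confidence level whose
interval excludes zero, mirroring the dagger/double-dagger/section symbol
convention. No multiple-testing correction is applied across the many
group-level fits — the suites report unadjusted tiers, and users should
read them accordingly.

`run_its_suite()` repeats the fit for every group and intervention
variant, logging per-run observation counts and skipping (with a reason)
groups whose series have fewer than three points on either side of the
cutoff.

## The in-sample forecast event model

The counterfactual regression is `y_it = x_it' beta + e_it` fitted by OLS
on pre-cutoff country-years only. The specification is chosen by k-fold
cross-validation (`select_spec_kfold()`) among a candidate family built
from the panel's covariates: main effects, interactions with a numeric
year index, and interactions with country indicators. Design decisions:

* **k = 5** by default, with a mandatory seed; folds partition
  country-year observations (not whole countries), because the task is to
  predict the same countries' futures, not to transfer to unseen
  countries. `k = n` reproduces leave-one-out exactly (tested against the
  hat-matrix identity).
* Ties in cross-validation score (within numerical noise) go to the
  candidate with fewest terms.
* Calendar-year **indicator** interactions are excluded from the shipped
  family: a dummy for an unseen post-cutoff year cannot be extrapolated,
  so such candidates cannot forecast. The numeric year index carries the
  trend instead; the family is configuration-driven, so any formula whose
  terms exist post-cutoff can be supplied.
* Countries with any missing covariate are excluded as complete cases
  (logged), the panel-data analogue of dropping a country for missing
  data.
* Distributed-lag robustness variants add one- or two-year **lagged
  covariates**, never lagged outcomes — a lagged outcome would absorb the
  very break under study.

Forecasts for post-cutoff years use each country's observed covariates;
aggregation uses the same population weights as the ITS stage. The
per-year prediction variance of the weighted aggregate is

$$
\widehat{\sigma}^2\left( \bar{x}_t' (X'X)^{-1} \bar{x}_t + \sum_i w_{it}^2 \right),
\qquad \bar{x}_t = \sum_i w_{it} x_{it},
$$

i.e. the exact linear-form variance of the weighted sum: the estimation
error of the common coefficient vector enters through the weighted mean
covariate vector, and the residual terms add under the assumption of
cross-country error independence. (Summing per-country prediction
variances would double-count the shared coefficient uncertainty; under
positive cross-country residual correlation the intervals here would be
too narrow — a documented limitation.) Intervals at 80/90/95% use the t
distribution on the pre-period residual degrees of freedom, and their
coverage is verified by simulation. The gap series is
`actual - counterfactual`, per year.

`run_event_suite()` refits the model within each group (global, income
tiers, regions) rather than reusing global coefficients — segmentation is
a genuine refit — and runs the lag, unweighted and exclusion variants
non-fatally.

## The synthetic-data generator

`generate_panel()` emulates the statistical structure the two designs
assume, with every injected parameter recorded in a `sim_truth` sidecar:

* **Defaults as study conditions**: 71 countries, annual data 1970-2015,
  four strata with heterogeneous near-linear trends (a declining
  high-income/OECD stratum, a rising upper-middle-income Asian stratum,
  and slowly moving lower-middle and low-income strata), a 2003
  intervention, ratification staggered 1-5 years later, about 2% of
  country-years missing (never a country's first year, so differencing
  keeps its anchor).
* **Breaks on the differenced scale**: `level_change` and `slope_change`
  act on annual changes from the year after the intervention, so the ITS
  truth is directly the injected numbers.
* **Covariates** are AR(1) within country (coefficient 0.8, marginal sd
  0.3) around country-specific means centred at 1 — slow-moving national
  indicators of the economy/development type. Their effects enter the
  outcome level linearly.
* **Noise**: the default is random-walk innovations (`noise =
  "random_walk"`, sd 30 cigarettes/adult/year): levels are unit-root
  non-stationary — as observed consumption series are — and the
  differenced residuals are iid, which is the regime the segmented
  regression assumes. `noise = "iid"` puts independent noise on levels
  instead, the regime under which the event regression model is exactly
  correct; the event-model calibration studies use it. This switch exists
  because no single noise process makes both estimators' textbook
  assumptions hold simultaneously, and calibration should be assessed
  under each estimator's own model.
* Outcomes are truncated at zero (consumption cannot be negative); with
  the default baselines truncation is vanishingly rare.

`generate_covariate_shift_panel()` breaks the event model's core
assumption on purpose: covariate effects change by a known amount after
the cutoff (per stratum if desired), creating a forecast gap of known
size. Since covariates are centred at 1, a total shift of `+150` yields a
mean gap of 150 cigarettes/adult/year.

What the generator does **not** emulate: population growth (populations
are constant per country, isolating consumption dynamics from
compositional drift), measurement-error spikes, policy-driven covariate
feedback, and cross-country residual correlation. Passing the package's
simulation tests therefore demonstrates the estimators' internal
correctness and calibration under their assumed data-generating
processes, not that those assumptions hold in any real panel.

## Validation studies and problem sizes

The test suite (and `scripts/acceptance.R`, which recomputes the same
quantities from scratch) runs these studies, sized to keep the whole suite
under a minute of Monte-Carlo work:

* **Exactness**: segmented-regression coefficients and classical SEs
  match a closed-form `(X'X)^{-1} X'y` oracle to `1e-10`; noiseless
  injected breaks are recovered exactly; the Dickey-Fuller statistic
  equals a brute-force two-variable regression t-ratio.
* **ITS recovery and coverage**: 200 panels (40 countries, 1970-2015,
  injected level change 24 and trend change 1.7 on the differenced scale,
  innovation sd 30, no covariates or missingness so the estimator is
  assessed under its own error model): mean estimates within Monte-Carlo
  error of truth, 95% CI coverage within [92%, 98%].
* **Type-I calibration**: 1000 null panels; 95%-tier false positives for
  the level change within [3%, 7%].
* **Dickey-Fuller size/power**: 100 series of length 200; white noise
  rejected at the 1% bracket in at least 95 of 100, random walks rejected
  at 5% in at most 10 of 100.
* **Event model**: zero gap with degenerate intervals on noiseless
  correctly specified data; a +150 injected shift recovered exactly
  (against a weighted-mean oracle) noiselessly and within two standard
  errors over 50 noisy seeds; 95% prediction-interval coverage of the
  aggregate within [92%, 98%] over 200 seeds; no-leakage (post-cutoff
  outcome edits leave the fitted coefficients bit-identical).
* **Masking**: two strata given offsetting +-150 shifts cancel in the
  global gap while stratified analyses recover both — the qualitative
  structure that motivates always pairing global results with stratified
  ones.

## Numerical and degenerate-input choices

Saturated (noiseless) fits are legitimate and return zero standard
errors, degenerate intervals, and a 99 tier for any nonzero coefficient.
Aliased columns in an event-model design (e.g. a constant covariate) are
dropped via the QR pivot and forecasting proceeds on the identified
subspace; a candidate that is rank deficient in any CV training fold is
skipped with a warning. Dickey-Fuller refuses constant series and series
shorter than 8; `fit_its()` refuses fewer than 3 observations on either
side of the cutoff. All seeded operations restore the caller's RNG state.

## Known limitations

* Prediction intervals assume cross-country residual independence;
  common shocks would make them anti-conservative.
* ITS significance tiers are unadjusted across groups and variants.
* The generator's covariates are generic AR(1) indicators; nothing is
  claimed about the realism of any particular covariate set, and
  conclusions about real data rest on the user's covariates satisfying
  the stable-correlation assumption.
* No imputation: missing country-years simply drop out of the per-year
  weights, which changes group composition over time in unbalanced
  panels (logged, not corrected).
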