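---
title: "Methods: search-volume decomposition and disease-rate surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: search-volume decomposition and disease-rate surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsvtrend)
```

## The problem

Registry statistics for chronic diseases such as lung cancer arrive roughly
three years after the fact. Relative search volumes (RSVs) — the 0-100
integer scale on which Google Trends reports how often a query was searched
in a region, with the window maximum pinned at 100 — are available in near
real time. The analysis this package implements asks whether state-level
monthly RSVs carry enough signal about registry incidence and mortality
rates to serve as a surveillance proxy, and whether isolating the long-term
trend of the search series strengthens that association.

The pipeline has four stages: simulate (or load) a panel, decompose each
monthly series under a multiplicative model, correlate original and
decomposed search volumes with annual rates per state, and extrapolate the
rates linearly past the registry lag.

## The multiplicative model

A monthly series is modelled as

$$Y(t) = T(t)\cdot S(m(t))\cdot C(t)\cdot I(t),$$

long-term trend × seasonal index of the calendar month × low-frequency
cycle × irregular factor. A multiplicative (rather than additive) form is
appropriate for search volumes because seasonal swings and noise scale with
the level of the series, and the 0-100 normalization is itself
multiplicative: rescaling a series by any positive constant leaves every
component ratio unchanged, and `decompose_rsv()` is invariant to such
rescaling.

Estimation in `decompose_rsv()`:

1. **Zero guard.** Zero observations (the scale's `"<1"` suppression) are
   replaced by 0.5 *for ratio computations only*; the reported `observed`
   vector is untouched. The multiplicative model is undefined at 0, and 0.5
   is the midpoint of the suppressed bin.
2. **Smoothing.** A 2×12 centered moving average (weights
   `(1/2, 1, ..., 1, 1/2)/12`), the standard even-period smoother that
   centers exactly on calendar months; the first and last six months are
   undefined. The smoother reproduces constants and linear trends exactly.
3. **Seasonal indices.** The monthly-average method: the observed/smoothed
   ratio is averaged per calendar month and the twelve raw indices are
   rescaled to mean exactly 1.
4. **Trend.** Least-squares polynomials of degree 1, 2 and 3 on the time
   index, fitted to the deseasonalized series via column-scaled QR; the
   selected degree maximizes adjusted R², with ties (within 1e-9) broken
   toward the lowest degree so that an exact line is reported as degree 1.
   Fitted values are floored at 1e-6 to keep the model defined.
5. **Cycle.** A 13-month centered running mean of the trend- and
   season-adjusted ratio `Y/(S\cdot T)`; 13 is the odd window closest to one
   year, so seasonal residue averages out while multi-year swings pass. The
   six edge months where the window does not fit carry `C = 1` by
   convention.
6. **Irregular.** `I = Y/(T·S·C)`, so the reconstruction `T·S·C·I = Y` is
   exact (to machine precision) wherever `Y > 0`.

### The fixed-point refinement

The one-pass ratio-to-moving-average seasonal estimate is biased when a
sloped trend multiplies a non-constant seasonal pattern: the 2×12 average of
$T(t)S(m)$ equals $T(t) + b\,\delta(m)$ with
$\delta(m)=\sum_k w_k\,k\,S(m+k)\neq 0$, a phase-dependent leakage of the
slope into the indices of order 1e-3 at this package's default scales. By
default (`refine = TRUE`) steps 3-5 are therefore iterated: the indices are
re-estimated as rescaled monthly means of $Y/(T\cdot C)$, with $C$ rebuilt
from $Y/(S\cdot T)$, until the indices change by less than 1e-11 (at most
40 iterations; typically 8-10). On a noiseless multiplicative series the
generating $(T, S)$ is an *exact* fixed point of this iteration, which is
what makes ground-truth recovery to 1e-6 and better a meaningful test.
`refine = FALSE` keeps the literal one-pass pipeline (with the cycle taken
from the smoothed/trend ratio) for comparison.

### Quantization

Integer rounding of the 0-100 scale perturbs each observation by up to 0.5,
i.e. ~0.5% relative at typical levels, so seasonal recovery from quantized
series is accurate only to about that order no matter the estimator. Exact
recovery checks therefore use the generator's `quantize = FALSE` output (the
continuous 0-100 rescaling); the package's tests assert 1e-6 recovery on
continuous series and ~2e-2 on integer series.

## The synthetic panel generator

`panel_config()` fixes the study conditions; `simulate_panel()` draws the
panel. The generator emulates a 51-state monthly panel (2004 onward) of the
kind a Trends export plus a registry extract produces. Defaults, with
rationale:

| parameter | default | meaning |
|---|---|---|
| `n_states` | 51 | US states plus DC |
| `start_year`, `end_year` | 2004, 2015 | earliest Trends year; registry deadline |
| `trend_intercept`, `trend_slope` | 70, −0.15/month | latent interest declining ~25% over 12 years, matching the downward drift of both lung-cancer rates and its search interest |
| `seasonal_indices` | `1 + 0.06·cos(2π(m−11)/12)` | ±6% annual pattern peaking in November (awareness-month timing); mean exactly 1 |
| `cycle_amplitude`, `cycle_period_months` | 0.05, 48 | mild 4-year swing standing in for news-driven multi-year waves |
| `irregular_sd` | 0.05 | ~5% month-to-month multiplicative noise, `I = exp(N(0, sd))` so positivity is automatic |
| `rate_link_strength` | 0.8 | strong but imperfect trend-rate dependence, in line with rank correlations of 0.6-0.95 |
| `rate_base`, `rate_scale` | 60, 6 per 100,000 | lung-cancer-like rate levels |

Per-unit heterogeneity is fixed generator behaviour rather than a knob:
each unit's intercept and slope get log-normal jitter (sd 0.08 and 0.12)
and the cycle a uniform phase, all drawn from seeded substreams so that
`simulate_rsv_series(config, i)` is deterministic regardless of call order;
the draws are returned in the panel's `truth` table. Annual rates are
`rate_base + rate_scale·(link·z + e)` with `z` the standardized annual mean
of the unit's latent trend and `e ~ N(0, 1−link²)`, floored at 0.1: at
`link = 1` the rates are a noiseless strictly monotone transform of the
annual trend level (so the decomposed-trend Spearman correlation is exactly
1 in annual-aggregate mode), and at `link = 0` they are independent noise,
giving a null calibration target of α.

What the generator does **not** emulate: Google's sampling variability
between downloads, celebrity-news spikes, the `"health"` category filter,
spatial correlation between neighbouring states, and any feedback from
rates to searches. Passing tests on this panel show the estimators recover
the structure they assume; they do not certify behaviour on real exports
with those artefacts.

## Correlation analysis

`merge_rates_with_rsv()` aligns annual rates with monthly RSVs per state.
Two modes are computed throughout, because the effective sample size per
state is a genuine modelling fork:

* **monthly-replicate** (headline mode) repeats each annual rate across its
  12 months — the row accounting that makes a 51-state 2004-2015 panel 144
  rows per state and 7344 in total — but inflates the t-test's n twelvefold
  with pseudo-replicates;
* **annual-aggregate** pairs the within-year RSV mean with the rate, one
  row per year (n = 12 at study scale), statistically the defensible
  choice.

Every output row carries its mode. `spearman_rho()` ranks with average-rank
ties and takes the Pearson correlation of ranks; significance uses the
two-tailed Student t statistic on n−2 degrees of freedom (`|ρ| = 1` maps to
p = 0), with an optional seeded permutation p-value as a small-sample
check. Per-state significance is judged at α = .05 with **no**
multiple-testing correction — that is how significant-state counts are
conventionally reported in this literature — but a Benjamini-Hochberg
adjusted column is emitted alongside so the reader can see what correction
would do; it never drives the `significant` flag. States with constant
rates over the window are flagged undefined and excluded from counts, which
therefore conserve: significant + non-significant + undefined = total.

The "decomposed" RSV variant is the fitted long-term trend `T(t)`: the
decomposition's purpose in this design is to strip seasonal, cyclical and
irregular variation so that the trend-level association with slowly-moving
annual rates stands out.

## Forecasting

`linear_forecast()` regresses rate on calendar year (OLS; years centered
internally for conditioning, coefficients reported on the raw scale, which
changes nothing in exact arithmetic) and extrapolates the configured
horizon — three years by default, bridging a 2015 registry deadline to
2018. The predictor is deliberately calendar year only, not the RSV series:
search-assisted forecasting is a separate modelling question, out of scope
here. Negative extrapolations are clamped to 0 and flagged. On rates lying
exactly on a line the predictions are exact (e.g. `80 − 1.5·(year−2004)`
over 2004-2015 gives 62.0, 60.5, 59.0 for 2016-2018).

## Problem sizes and determinism

The shipped analyses use the study-scale panel (51 states, 180 months of
RSV, 12 rate years, forecasts over 3 held-out years); recovery checks use
single 144-month series; the null-calibration check uses 1000-1200
independent units in annual-aggregate mode, enough for a ±3-standard-error
band of about ±0.02 around α = .05. Every stochastic step draws from an
explicit seed (configs require one; substreams are derived per unit and
metric), and the orchestration layer writes byte-identical outputs for
identical inputs — `run_analyze()` composes the module operations and
computes nothing itself.

## Known limitations

* The cyclical component's sinusoidal form in the generator, and the
  13-month smoother extracting it, are declared conventions; real
  news-driven cycles are neither smooth nor periodic.
* The trend family is restricted to polynomials of degree ≤ 3. That is
  auditable and reproducible, but a series whose trend genuinely saturates
  (e.g. logistic) will be approximated, not matched.
* t-based Spearman p-values are approximate at n = 12 (annual-aggregate
  mode); the permutation option exists precisely for that range, and the
  null-calibration test shows the approximation's size error is within the
  Monte-Carlo band at α = .05.
* In monthly-replicate mode p-values are anti-conservative by construction
  (replicated rates); counts in that mode reproduce a reporting convention,
  not a calibrated test.
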