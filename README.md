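# rsvtrend

Search-volume time-series decomposition and disease-rate surveillance.

Cancer registries publish incidence and mortality statistics with a lag of
about three years, which leaves surveillance blind exactly where timeliness
matters. Infodemiology studies bridge that gap with internet search data:
Google Trends reports, for any region and window, the *relative search
volume* (RSV) of a query on a 0-100 integer scale (the window maximum is
100). If search interest in a disease tracks its real burden, then
state-level monthly RSVs should correlate with registry rates and can stand
in as a near-real-time proxy.

`rsvtrend` is a tested R implementation of that analysis for researchers in
digital epidemiology and cancer surveillance. It provides:

* **a synthetic panel generator** with known ground truth: per-state monthly
  RSVs built from the multiplicative composition
  `Y(t) = T(t) · S(month) · C(t) · I(t)` (linear latent trend, twelve
  seasonal indices with mean 1, a low-frequency sinusoidal cycle, log-normal
  irregular noise) and renormalized to 0-100, plus annual age-adjusted rates
  per 100,000 whose dependence on each state's latent trend is a simulation
  parameter (`rate_link_strength`), so the correlation the analysis should
  find is known in advance;
* **classical multiplicative decomposition** of a monthly series: 2×12
  centered moving-average smoothing, monthly-average seasonal indices
  (refined to their exact fixed point, so noiseless ground truth is
  recovered to numerical precision), polynomial long-term trend of degree
  1-3 selected by adjusted R², a 13-month cyclical smoother, and the
  irregular residual — with the reconstruction `T·S·C·I = Y` exact wherever
  `Y > 0`;
* **per-state Spearman correlation** of original and decomposed (long-term
  trend) RSVs against annual incidence and mortality, with two-tailed
  Student-t p-values at α = .05, significant-state counting, and two
  alignment modes (`monthly-replicate`, which reproduces the 144 rows per
  state / 7344 total accounting of a 51-state 2004-2015 panel, and
  `annual-aggregate`, which avoids the 12-fold pseudo-replication of annual
  rates);
* **simple linear extrapolation** of annual rates past the registry lag
  (rate on calendar year, per state and metric), with negative predictions
  clamped and flagged.

## Worked example

```r
library(rsvtrend)

cfg <- panel_config(n_states = 3, start_year = 2004, end_year = 2015, seed = 42)
panel <- simulate_panel(cfg)
panel$rsv$Alabama
#> <rsv_series> Alabama: 144 months (2004-01 to 2015-12), range [57, 100]

d <- decompose_rsv(panel$rsv$Alabama)
d
#> <rsv_decomposition> Alabama: 144 months; trend degree 3 (adj R2 0.6806); seasonal range [0.921, 1.069]
round(d$seasonal_indices, 3)
#>  [1] 1.034 1.010 0.973 0.951 0.952 0.921 0.943 0.995 1.069 1.026 1.069 1.057

dec <- lapply(panel$rsv, decompose_rsv)
merged <- merge_rates_with_rsv(panel$rsv, dec, panel$rates, mode = "annual-aggregate")
summarize_correlations(correlate_states(merged))[, 1:6]
#>   rsv_variant    metric   alignment_mode n_significant n_total n_undefined
#> 1    original incidence annual-aggregate             3       3           0
#> 2    original mortality annual-aggregate             3       3           0
#> 3  decomposed incidence annual-aggregate             3       3           0
#> 4  decomposed mortality annual-aggregate             3       3           0

linear_forecast(panel$rates$Alabama.incidence, 3)
#> <forecast_result> Alabama incidence: fit 2004-2015, slope -1.661/yr; predicted 2016: 47.3, 2017: 45.6, 2018: 44.0
```

Reading the output: the simulated Alabama series spans 144 months; its
seasonal indices peak in the late-autumn months (the generator's default
pattern peaks in November) and the fitted long-term trend declines, so the
annual rates — linked to that trend at the default strength 0.8 — correlate
significantly with both RSV variants in every state of this small panel.
The forecast extends Alabama's declining incidence line (−1.66 per 100,000
per year) three years past the 2015 registry deadline.

## The analysis workflow

The `analysis/` scripts run the full study on a 51-state panel (monthly
RSVs 2004-2018, rates analyzed through 2015, forecasts 2016-2018):

```sh
Rscript analysis/01_simulate.R    # panel -> results/data/
Rscript analysis/02_decompose.R   # components -> results/decomposition/
Rscript analysis/03_correlate.R   # correlations -> results/correlation/
Rscript analysis/04_forecast.R    # extrapolations -> results/forecast/
```

`run_simulate()` and `run_analyze()` expose the same orchestration as
package functions.

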