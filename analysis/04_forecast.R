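#!/usr/bin/env Rscript
# Step 4: linear extrapolation of the annual rates past the registry lag.
#
# Fits rate ~ year per state and metric on 2004-2015 and predicts 2016-2018.
# Because the panel simulates rates through 2018, the held-out years provide
# a direct check of how far the simple linear bridge drifts.

library(rsvtrend)

rates <- read_rates_csv("results/data/rates.csv")
fit_rates <- lapply(rates, function(r) {
  rate_series(r$unit, r$metric, r$years[r$years <= 2015],
              r$rates[r$years <= 2015])
})
forecasts <- forecast_panel(fit_rates, horizon_years = 3)

dir.create("results/forecast", recursive = TRUE, showWarnings = FALSE)
write_table_csv(forecasts_to_df(forecasts), "results/forecast/forecasts.csv")

holdout <- do.call(rbind, lapply(names(forecasts), function(nm) {
  fc <- forecasts[[nm]]
  src <- rates[[nm]]
  truth <- src$rates[match(fc$predicted$year, src$years)]
  data.frame(unit = fc$unit, metric = fc$metric, year = fc$predicted$year,
             predicted_rate = fc$predicted$rate, actual_rate = truth,
             error = fc$predicted$rate - truth, stringsAsFactors = FALSE)
}))
write_table_csv(holdout, "results/forecast/holdout_comparison.csv")

rmse <- sqrt(mean(holdout$error^2))
message(sprintf("forecast %d series 2016-2018; held-out RMSE %.2f per 100,000 (mean in-sample RMSE %.2f)",
                length(forecasts), rmse,
                mean(vapply(forecasts, `[[`, numeric(1), "in_sample_rmse"))))
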