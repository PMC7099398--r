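#!/usr/bin/env Rscript
# Step 2: multiplicative decomposition of every state's search-volume series.
#
# Each monthly series is split into long-term trend, seasonal, cyclical and
# irregular components (Y = T * S * C * I): 2x12 centered moving average,
# monthly-average seasonal indices refined to their fixed point, polynomial
# trend (degree 1-3 by adjusted R^2), 13-month cyclical smoother.

library(rsvtrend)

rsv_files <- sort(list.files("results/data", pattern = "^rsv_", full.names = TRUE))
series <- lapply(rsv_files, read_rsv_csv)
decomps <- lapply(series, decompose_rsv)

dir.create("results/decomposition", recursive = TRUE, showWarnings = FALSE)
components <- do.call(rbind, lapply(decomps, function(d) {
  cbind(unit = d$unit, as.data.frame(d), stringsAsFactors = FALSE)
}))
write_table_csv(components, "results/decomposition/components.csv")

seasonal <- do.call(rbind, lapply(decomps, function(d) {
  data.frame(unit = d$unit, month = 1:12, seasonal_index = d$seasonal_indices,
             stringsAsFactors = FALSE)
}))
write_table_csv(seasonal, "results/decomposition/seasonal_indices.csv")

for (d in decomps) {
  write_trend_model(d$trend_model,
                    file.path("results/decomposition",
                              paste0("trend_model_", gsub("[^a-z0-9]+", "_",
                                                          tolower(d$unit)), ".txt")))
}

degrees <- vapply(decomps, function(d) d$trend_model$degree, integer(1))
peak <- vapply(decomps, function(d) which.max(d$seasonal_indices), integer(1))
message(sprintf("decomposed %d states: trend degrees %s; modal seasonal peak month %d",
                length(decomps),
                paste(names(table(degrees)), table(degrees), sep = "x", collapse = ", "),
                as.integer(names(which.max(table(peak))))))
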