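#!/usr/bin/env Rscript
# Step 1: simulate the study panel.
#
# 51 state-level units with monthly relative search volumes (0-100 integer
# scale) from January 2004 through December 2018, plus annual age-adjusted
# incidence and mortality rates per 100,000 for the same years. The rates are
# tied to each state's latent search-interest trend with link strength 0.8,
# so downstream correlation analyses have a known positive signal to find.

library(rsvtrend)

cfg <- panel_config(
  n_states = 51,
  start_year = 2004, end_year = 2018,
  seed = 20040103
)

manifest <- run_simulate(cfg, "results/data")

message(sprintf("wrote %d files; %d monthly RSV rows, %d annual rate rows",
                nrow(manifest),
                sum(manifest$n_rows[grepl('^rsv_', manifest$file)]),
                manifest$n_rows[manifest$file == "rates.csv"]))
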