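#!/usr/bin/env Rscript
# Step 3: per-state Spearman correlation of search volumes with disease rates.
#
# Rates are available only through the 2015 registry deadline, so the merge is
# restricted to 2004-2015 (144 monthly rows per state, 7344 in total in
# monthly-replicate mode). Both RSV variants (original values and decomposed
# long-term trend) are correlated against incidence and mortality, in both
# alignment modes, with two-tailed t significance at alpha = .05.

library(rsvtrend)

series <- lapply(sort(list.files("results/data", pattern = "^rsv_",
                                 full.names = TRUE)), read_rsv_csv)
rates <- read_rates_csv("results/data/rates.csv")
decomps <- lapply(series, decompose_rsv)

dir.create("results/correlation", recursive = TRUE, showWarnings = FALSE)
all_res <- list()
for (mode in c("monthly-replicate", "annual-aggregate")) {
  panel <- merge_rates_with_rsv(series, decomps, rates, mode = mode,
                                start_year = 2004, end_year = 2015)
  if (mode == "monthly-replicate") {
    message(sprintf("merged panel: %d rows (%d per state)",
                    nrow(panel), nrow(panel) / length(series)))
  }
  all_res[[mode]] <- correlate_states(panel, alpha = 0.05)
}
correlations <- do.call(rbind, unname(lapply(all_res, as.data.frame)))
summary_tab <- do.call(rbind, unname(lapply(all_res, summarize_correlations)))
write_table_csv(correlations, "results/correlation/correlations.csv")
write_table_csv(summary_tab, "results/correlation/summary.csv")

hl <- summary_tab[summary_tab$alignment_mode == "monthly-replicate", ]
for (i in seq_len(nrow(hl))) {
  message(sprintf("%s RSV vs %s: significant in %d of %d states%s",
                  hl$rsv_variant[i], hl$metric[i], hl$n_significant[i],
                  hl$n_total[i],
                  ifelse(nzchar(hl$non_significant_units[i]),
                         paste0(" (not: ", hl$non_significant_units[i], ")"), "")))
}
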