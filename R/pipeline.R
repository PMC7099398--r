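#' Simulate a panel and write it to disk
#'
#' Generates the configured panel and writes, under `out_dir`: one RSV file
#' per unit (`rsv_<slug>.csv`, Google-Trends dialect), the annual rates in
#' long format (`rates.csv`), the per-unit ground truth (`truth.csv`), and a
#' `manifest.csv` listing every file with its data row count. Outputs are
#' byte-deterministic given the config.
#'
#' @param config A [panel_config] or the path to a YAML file for
#'   [read_panel_config].
#' @param out_dir Output directory (created if needed).
#' @param quantize Passed to [simulate_panel].
#' @return Invisibly, the manifest data frame.
#' @export
run_simulate <- function(config, out_dir, quantize = TRUE) {
  if (is.character(config)) config <- read_panel_config(config)
  stopifnot(inherits(config, "panel_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- simulate_panel(config, quantize = quantize)
  files <- character(0)
  nrows <- integer(0)
  for (s in panel$rsv) {
    f <- paste0("rsv_", unit_slug(s$unit), ".csv")
    write_rsv_csv(s, file.path(out_dir, f))
    files <- c(files, f); nrows <- c(nrows, length(s$value))
  }
  write_rates_csv(panel$rates, file.path(out_dir, "rates.csv"))
  files <- c(files, "rates.csv")
  nrows <- c(nrows, sum(vapply(panel$rates, function(r) length(r$years), integer(1))))
  write_table_csv(panel$truth, file.path(out_dir, "truth.csv"))
  files <- c(files, "truth.csv"); nrows <- c(nrows, nrow(panel$truth))
  manifest <- data.frame(file = files, n_rows = nrows, stringsAsFactors = FALSE)
  write_table_csv(manifest, file.path(out_dir, "manifest.csv"))
  message(sprintf("simulated %d units (%d-%d) into %s",
                  config$n_states, config$start_year, config$end_year, out_dir))
  invisible(manifest)
}

unit_slug <- function(unit) gsub("[^a-z0-9]+", "_", tolower(unit))

read_rsv_dir <- function(path) {
  files <- sort(list.files(path, pattern = "^rsv_.*\\.csv$", full.names = TRUE))
  if (length(files) == 0L) stop("no rsv_*.csv files in ", path)
  lapply(files, read_rsv_csv)
}

#' Run the full search-volume surveillance analysis
#'
#' End-to-end composition of the package's modules on a panel of monthly RSV
#' series and annual rates: decompose every unit's series, merge with the
#' rates in both alignment modes, correlate per state (original and
#' decomposed variants against incidence and mortality), extrapolate the
#' rates past the analysis window, and write all result tables under
#' `out_dir`:
#'
#' * `components.csv` — long decomposition table over all units;
#' * `trend_models.csv` — fitted trend curve per unit;
#' * `correlations.csv` — one row per unit, RSV variant, metric and mode;
#' * `summary.csv` — significant-state counts per pairing and mode;
#' * `forecasts.csv` — linear extrapolations with coefficients;
#' * `run_log.txt` — configuration and estimation conventions used.
#'
#' This function only composes the module operations; it performs no
#' computation of its own, and identical inputs yield byte-identical output
#' files.
#'
#' @param rsv List of [rsv_series], or a directory containing `rsv_*.csv`.
#' @param rates List of [rate_series], or the path of a long-format CSV.
#' @param out_dir Output directory (created if needed).
#' @param start_year,end_year Analysis window for the correlation and
#'   forecast fit (defaults: full overlap of the rates). Rates are restricted
#'   to the window; RSV months outside it still inform the decomposition.
#' @param alpha Significance level for the per-state flags.
#' @param horizon_years Forecast horizon past `end_year`.
#' @param modes Alignment modes to compute (both by default; the first is
#'   the headline mode listed first in `summary.csv`).
#' @return Invisibly, a list with `decompositions`, `panels`, `correlations`,
#'   `summary`, `forecasts`.
#' @export
run_analyze <- function(rsv, rates, out_dir,
                        start_year = NULL, end_year = NULL,
                        alpha = 0.05, horizon_years = 3L,
                        modes = c("monthly-replicate", "annual-aggregate")) {
  if (is.character(rsv)) rsv <- read_rsv_dir(rsv)
  if (inherits(rsv, "rsv_series")) rsv <- list(rsv)
  if (is.character(rates)) rates <- read_rates_csv(rates)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!is.null(start_year) && !is.null(end_year) && start_year > end_year) {
    stop("start_year must be <= end_year")
  }
  modes <- match.arg(modes, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  decomps <- lapply(rsv, decompose_rsv)
  comp <- do.call(rbind, lapply(decomps, function(d) {
    cbind(unit = d$unit, as.data.frame(d), stringsAsFactors = FALSE)
  }))
  write_table_csv(comp, file.path(out_dir, "components.csv"))
  models <- do.call(rbind, lapply(decomps, function(d) {
    cf <- rep(NA_real_, 4)
    cf[seq_along(d$trend_model$coefficients)] <- d$trend_model$coefficients
    data.frame(unit = d$unit, family = d$trend_model$family,
               degree = d$trend_model$degree,
               coef_0 = cf[1], coef_1 = cf[2], coef_2 = cf[3], coef_3 = cf[4],
               adj_r_squared = d$trend_model$adj_r_squared,
               stringsAsFactors = FALSE)
  }))
  write_table_csv(models, file.path(out_dir, "trend_models.csv"))

  panels <- list()
  cors <- list()
  sums <- list()
  for (m in modes) {
    panel <- merge_rates_with_rsv(rsv, decomps, rates, mode = m,
                                  start_year = start_year, end_year = end_year)
    res <- correlate_states(panel, alpha = alpha)
    panels[[m]] <- panel
    cors[[m]] <- res
    sums[[m]] <- summarize_correlations(res)
  }
  correlations <- do.call(rbind, unname(lapply(cors, as.data.frame)))
  summary_tab <- do.call(rbind, unname(sums))
  write_table_csv(correlations, file.path(out_dir, "correlations.csv"))
  write_table_csv(summary_tab, file.path(out_dir, "summary.csv"))

  fit_rates <- lapply(rates, function(r) {
    keep <- rep(TRUE, length(r$years))
    if (!is.null(start_year)) keep <- keep & r$years >= start_year
    if (!is.null(end_year)) keep <- keep & r$years <= end_year
    if (!any(keep)) return(NULL)
    rate_series(r$unit, r$metric, r$years[keep], r$rates[keep])
  })
  fit_rates <- Filter(Negate(is.null), fit_rates)
  forecasts <- forecast_panel(fit_rates, horizon_years = horizon_years)
  write_table_csv(forecasts_to_df(forecasts), file.path(out_dir, "forecasts.csv"))

  writeLines(c(
    "rsvtrend analysis run",
    paste0("package_version: ", as.character(utils::packageVersion("rsvtrend"))),
    paste0("n_units: ", length(rsv)),
    paste0("analysis_window: ", if (is.null(start_year)) "panel" else start_year,
           "-", if (is.null(end_year)) "panel" else end_year),
    paste0("alpha: ", format_num(alpha)),
    paste0("alignment_modes: ", paste(modes, collapse = ",")),
    paste0("horizon_years: ", horizon_years),
    "conventions: multiplicative model; 2x12 centered MA; monthly-average seasonal index (fixed-point refinement); polynomial trend degree 1-3 by adjusted R2; 13-month cyclical smoother; two-tailed t p-values"
  ), file.path(out_dir, "run_log.txt"), useBytes = TRUE)

  message(sprintf("analyzed %d units; results in %s", length(rsv), out_dir))
  invisible(list(decompositions = decomps, panels = panels,
                 correlations = correlations, summary = summary_tab,
                 forecasts = forecasts))
}
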