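#' Configuration for a synthetic search-volume / disease-rate panel
#'
#' Defines the ground truth of a simulated state-level panel: each unit's
#' monthly latent search interest is the multiplicative composition
#' `T(t) * S(month) * C(t) * I(t)` of a linear long-term trend, twelve
#' seasonal indices with mean 1, a smooth low-frequency cycle
#' `1 + cycle_amplitude * sin(2*pi*t/cycle_period_months + phase)`, and
#' log-normal irregular noise `exp(N(0, irregular_sd))`; the series is then
#' renormalized to the 0-100 relative scale. Annual rates are built from the
#' unit's standardized annual trend level with dependence strength
#' `rate_link_strength`, so the correlation the downstream analysis should
#' find is a known simulation parameter.
#'
#' Units differ through seeded per-unit jitter of the trend parameters
#' (log-normal, sd 0.08 on the intercept and 0.12 on the slope) and a uniform
#' cycle phase; these per-unit draws are part of the recorded ground truth.
#'
#' @param n_states Number of geographic units (51 = US states plus DC).
#' @param start_year,end_year Inclusive calendar years of the panel.
#' @param trend_intercept,trend_slope Latent trend `intercept + slope * t`
#'   per month `t = 1, 2, ...` before normalization; must stay positive over
#'   the horizon.
#' @param seasonal_indices Twelve positive multiplicative month factors with
#'   mean 1 (within 1e-9). Default: a mild cosine pattern peaking in November.
#' @param cycle_amplitude Dimensionless cycle amplitude in `[0, 1)`.
#' @param cycle_period_months Cycle period, an integer `>= 24`, or `NULL`
#'   when `cycle_amplitude = 0`.
#' @param irregular_sd Standard deviation of the log irregular factor.
#' @param rate_link_strength Dependence in `[-1, 1]` between a unit's latent
#'   annual trend level and its annual rates; contamination noise has
#'   standard deviation `sqrt(1 - rate_link_strength^2)`, so 1 means a
#'   noiseless monotone link and 0 means no association.
#' @param rate_base,rate_scale Location and scale of the annual rates, per
#'   100,000.
#' @param seed Integer RNG seed (mandatory; all panel randomness derives
#'   from it).
#' @return An object of class `panel_config`.
#' @examples
#' cfg <- panel_config(n_states = 2, seed = 1)
#' @export
panel_config <- function(n_states = 51L,
                         start_year = 2004L, end_year = 2015L,
                         trend_intercept = 70, trend_slope = -0.15,
                         seasonal_indices = default_seasonal_indices(),
                         cycle_amplitude = 0.05, cycle_period_months = 48L,
                         irregular_sd = 0.05,
                         rate_link_strength = 0.8,
                         rate_base = 60, rate_scale = 6,
                         seed) {
  if (missing(seed)) stop("seed is mandatory: all panel randomness derives from it")
  n_states <- as.integer(n_states)
  if (is.na(n_states) || n_states < 1L) stop("n_states must be a positive integer")
  start_year <- as.integer(start_year); end_year <- as.integer(end_year)
  if (end_year < start_year) stop("end_year must be >= start_year")
  if (!is.numeric(trend_intercept) || trend_intercept <= 0) {
    stop("trend_intercept must be positive")
  }
  seasonal_indices <- as.numeric(seasonal_indices)
  if (length(seasonal_indices) != 12L || any(seasonal_indices <= 0)) {
    stop("seasonal_indices must be 12 positive factors")
  }
  if (abs(mean(seasonal_indices) - 1) > 1e-9) {
    stop("seasonal_indices must have mean 1 (within 1e-9)")
  }
  if (cycle_amplitude < 0 || cycle_amplitude >= 1) {
    stop("cycle_amplitude must be in [0, 1)")
  }
  if (cycle_amplitude > 0) {
    if (is.null(cycle_period_months)) stop("cycle_period_months required when cycle_amplitude > 0")
    cycle_period_months <- as.integer(cycle_period_months)
    if (cycle_period_months < 24L) stop("cycle_period_months must be >= 24")
  }
  if (irregular_sd < 0) stop("irregular_sd must be >= 0")
  if (abs(rate_link_strength) > 1) stop("rate_link_strength must be in [-1, 1]")
  if (rate_base <= 0 || rate_scale <= 0) stop("rate_base and rate_scale must be positive")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  structure(list(
    n_states = n_states, start_year = start_year, end_year = end_year,
    trend_intercept = trend_intercept, trend_slope = trend_slope,
    seasonal_indices = seasonal_indices,
    cycle_amplitude = cycle_amplitude,
    cycle_period_months = cycle_period_months,
    irregular_sd = irregular_sd,
    rate_link_strength = rate_link_strength,
    rate_base = rate_base, rate_scale = rate_scale,
    seed = seed
  ), class = "panel_config")
}

#' @rdname panel_config
#' @details `default_seasonal_indices()` returns
#'   `1 + 0.06 * cos(2*pi*(m - 11)/12)`: a mild annual pattern whose peak
#'   month is November (awareness-month timing for lung cancer searches) and
#'   whose mean is exactly 1.
#' @export
default_seasonal_indices <- function() {
  1 + 0.06 * cos(2 * pi * ((1:12) - 11) / 12)
}

#' Read a panel configuration from a YAML file
#'
#' Keys mirror the [panel_config] argument names; omitted keys take the
#' defaults (the seed key is still mandatory).
#'
#' @param path YAML file path.
#' @return A `panel_config`.
#' @export
read_panel_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(panel_config)))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(panel_config, vals)
}

#' Unit labels for a synthetic panel
#'
#' For `n <= 51`, the US state names plus the District of Columbia in
#' alphabetical order (the paper-scale panel); beyond that, `unit_052` style
#' placeholders.
#'
#' @param n Number of units.
#' @return Character vector of length `n`.
#' @export
unit_labels <- function(n) {
  us <- sort(c(datasets::state.name, "District of Columbia"))
  if (n <= length(us)) return(us[seq_len(n)])
  c(us, sprintf("unit_%03d", seq(length(us) + 1L, n)))
}

n_months_of <- function(config) 12L * (config$end_year - config$start_year + 1L)

# Independent substreams per (seed, unit, stream); kept below 2^31.
mix_seed <- function(seed, unit_index, stream) {
  as.integer((as.double(seed) + 1000003 * unit_index + 97 * stream) %% 2147483647)
}

# Per-unit latent parameters; their draws are part of the ground truth.
unit_params <- function(config, unit_index) {
  withr::with_seed(mix_seed(config$seed, unit_index, 3L), {
    list(
      unit = unit_labels(config$n_states)[unit_index],
      trend_intercept = config$trend_intercept * exp(stats::rnorm(1, 0, 0.08)),
      trend_slope = config$trend_slope * exp(stats::rnorm(1, 0, 0.12)),
      cycle_phase = stats::runif(1, 0, 2 * pi)
    )
  })
}

check_unit_index <- function(config, unit_index) {
  unit_index <- as.integer(unit_index)
  if (is.na(unit_index) || unit_index < 1L || unit_index > config$n_states) {
    stop("unit_index must be in 1..n_states")
  }
  unit_index
}

latent_trend <- function(config, params) {
  tt <- seq_len(n_months_of(config))
  trend <- params$trend_intercept + params$trend_slope * tt
  if (any(trend <= 0)) {
    stop("invalid config: latent trend non-positive over the horizon for unit ",
         params$unit)
  }
  trend
}

#' Simulate one unit's monthly RSV series
#'
#' Composes the unit's latent multiplicative series
#' `T(t) * S(month) * C(t) * I(t)` and passes it through [rsv_normalize].
#' Deterministic given `(seed, unit_index)` regardless of call order.
#'
#' @param config A [panel_config].
#' @param unit_index Unit number in `1..n_states`.
#' @param quantize Passed to [rsv_normalize]; `FALSE` yields the continuous
#'   0-100 series (exact multiplicative structure preserved, used by
#'   ground-truth recovery analyses).
#' @return An [rsv_series] of length `12 * (end_year - start_year + 1)`.
#' @export
simulate_rsv_series <- function(config, unit_index, quantize = TRUE) {
  stopifnot(inherits(config, "panel_config"))
  unit_index <- check_unit_index(config, unit_index)
  params <- unit_params(config, unit_index)
  n <- n_months_of(config)
  tt <- seq_len(n)
  trend <- latent_trend(config, params)
  month <- (tt - 1L) %% 12L + 1L
  seasonal <- config$seasonal_indices[month]
  cyc <- if (config$cycle_amplitude > 0) {
    1 + config$cycle_amplitude *
      sin(2 * pi * tt / config$cycle_period_months + params$cycle_phase)
  } else rep(1, n)
  irr <- if (config$irregular_sd > 0) {
    withr::with_seed(mix_seed(config$seed, unit_index, 0L),
                     exp(stats::rnorm(n, 0, config$irregular_sd)))
  } else rep(1, n)
  latent <- trend * seasonal * cyc * irr
  rsv_series(params$unit,
             config$start_year + (tt - 1L) %/% 12L,
             month,
             rsv_normalize(latent, quantize = quantize))
}

annual_trend_level <- function(config, params) {
  trend <- latent_trend(config, params)
  years <- config$start_year:config$end_year
  vapply(seq_along(years), function(i) mean(trend[(12L * (i - 1L) + 1L):(12L * i)]),
         numeric(1))
}

#' Simulate one unit's annual rate series
#'
#' Annual age-adjusted rates per 100,000 with a configurable monotone
#' dependence on the unit's latent trend:
#' `rate = rate_base + rate_scale * (link * z + e)` where `z` is the
#' standardized annual mean of the latent trend, `e ~ N(0, 1 - link^2)`
#' contamination noise, and the result is floored at 0.1. With
#' `rate_link_strength = 1` the rates are a strictly monotone (affine)
#' transform of the annual trend level.
#'
#' @param config A [panel_config].
#' @param unit_index Unit number in `1..n_states`.
#' @param metric `"incidence"` or `"mortality"` (independent noise streams).
#' @return A [rate_series] with one rate per panel year.
#' @export
simulate_rate_series <- function(config, unit_index, metric) {
  stopifnot(inherits(config, "panel_config"))
  unit_index <- check_unit_index(config, unit_index)
  metric <- match.arg(metric, c("incidence", "mortality"))
  params <- unit_params(config, unit_index)
  level <- annual_trend_level(config, params)
  n_years <- length(level)
  z <- if (n_years > 1L && stats::sd(level) > 0) {
    (level - mean(level)) / stats::sd(level)
  } else rep(0, n_years)
  link <- config$rate_link_strength
  noise_sd <- sqrt(max(0, 1 - link^2))
  stream <- if (metric == "incidence") 1L else 2L
  e <- if (noise_sd > 0) {
    withr::with_seed(mix_seed(config$seed, unit_index, stream),
                     stats::rnorm(n_years, 0, noise_sd))
  } else rep(0, n_years)
  rates <- pmax(config$rate_base + config$rate_scale * (link * z + e), 0.1)
  rate_series(params$unit, metric, config$start_year:config$end_year, rates)
}

#' Simulate a full panel with ground truth
#'
#' One RSV series plus incidence and mortality rate series per unit, and the
#' per-unit ground-truth parameters actually used. Deterministic: the same
#' config (including seed) always yields an identical panel.
#'
#' @param config A [panel_config].
#' @param quantize Passed to [simulate_rsv_series].
#' @return A list with `rsv` (named list of [rsv_series]), `rates` (list of
#'   [rate_series] named `"unit.metric"`), `truth` (data frame of per-unit
#'   latent parameters) and `config`.
#' @export
simulate_panel <- function(config, quantize = TRUE) {
  stopifnot(inherits(config, "panel_config"))
  idx <- seq_len(config$n_states)
  params <- lapply(idx, function(i) unit_params(config, i))
  units <- vapply(params, `[[`, character(1), "unit")
  rsv <- lapply(idx, function(i) simulate_rsv_series(config, i, quantize = quantize))
  names(rsv) <- units
  rates <- list()
  for (i in idx) {
    for (m in c("incidence", "mortality")) {
      rates[[paste(units[i], m, sep = ".")]] <- simulate_rate_series(config, i, m)
    }
  }
  truth <- data.frame(
    unit = units,
    trend_intercept = vapply(params, `[[`, numeric(1), "trend_intercept"),
    trend_slope = vapply(params, `[[`, numeric(1), "trend_slope"),
    cycle_phase = vapply(params, `[[`, numeric(1), "cycle_phase"),
    stringsAsFactors = FALSE
  )
  list(rsv = rsv, rates = rates, truth = truth, config = config)
}
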