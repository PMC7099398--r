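#' Linear extrapolation of an annual rate series
#'
#' Ordinary least squares of the rate on calendar year, extrapolated
#' `horizon_years` past the last observed year — the simple linear prediction
#' used to bridge the multi-year registry lag. Years are centered at their
#' mean internally for numerical conditioning and the coefficients are
#' reported on the raw calendar-year scale; predictions are identical either
#' way. Negative extrapolations are clamped to 0 and flagged.
#'
#' @param rates A [rate_series] with at least 3 annual observations.
#' @param horizon_years Number of years to extrapolate (`>= 1`).
#' @return An object of class `forecast_result`: list with `unit`, `metric`,
#'   `fit_years`, `intercept`, `slope` (per-100,000 per year, raw-year
#'   scale), `predicted` (data frame `year`, `rate`, `clamped`), and
#'   `in_sample_rmse`.
#' @examples
#' r <- rate_series("Kentucky", "incidence", 2004:2015, 80 - 1.5 * (0:11))
#' linear_forecast(r, 3)$predicted$rate  # 62.0 60.5 59.0
#' @export
linear_forecast <- function(rates, horizon_years = 3L) {
  stopifnot(inherits(rates, "rate_series"))
  horizon_years <- as.integer(horizon_years)
  if (horizon_years < 1L) stop("horizon_years must be >= 1")
  n <- length(rates$years)
  if (n < 3L) stop("need at least 3 annual observations to fit a line")
  if (length(unique(rates$years)) < 2L) stop("constant years: degenerate fit")
  yc <- rates$years - mean(rates$years)
  slope <- sum(yc * (rates$rates - mean(rates$rates))) / sum(yc^2)
  intercept_centered <- mean(rates$rates)
  intercept <- intercept_centered - slope * mean(rates$years)
  fitted <- intercept_centered + slope * yc
  pred_years <- max(rates$years) + seq_len(horizon_years)
  pred <- intercept_centered + slope * (pred_years - mean(rates$years))
  clamped <- pred < 0
  pred <- pmax(pred, 0)
  structure(list(
    unit = rates$unit,
    metric = rates$metric,
    fit_years = rates$years,
    intercept = intercept,
    slope = slope,
    predicted = data.frame(year = pred_years, rate = pred, clamped = clamped),
    in_sample_rmse = sqrt(mean((rates$rates - fitted)^2))
  ), class = "forecast_result")
}

#' @export
print.forecast_result <- function(x, ...) {
  cat(sprintf("<forecast_result> %s %s: fit %d-%d, slope %+.3f/yr; predicted %s\n",
              x$unit, x$metric, min(x$fit_years), max(x$fit_years), x$slope,
              paste(sprintf("%d: %.1f", x$predicted$year, x$predicted$rate),
                    collapse = ", ")))
  invisible(x)
}

#' Extrapolate every rate series in a panel
#'
#' Applies [linear_forecast] per (unit, metric). Series failing its
#' preconditions (too few years) are reported with a warning and skipped.
#'
#' @param rates A list of [rate_series].
#' @param horizon_years Number of years to extrapolate.
#' @return A list of `forecast_result` objects (named as the input).
#' @export
forecast_panel <- function(rates, horizon_years = 3L) {
  if (inherits(rates, "rate_series")) rates <- list(rates)
  if (length(rates) == 0L) {
    warning("empty rates input: nothing to forecast")
    return(list())
  }
  stopifnot(all(vapply(rates, inherits, logical(1), "rate_series")))
  out <- list()
  skipped <- character(0)
  for (k in seq_along(rates)) {
    r <- rates[[k]]
    fc <- tryCatch(linear_forecast(r, horizon_years), error = function(e) NULL)
    if (is.null(fc)) {
      skipped <- c(skipped, paste(r$unit, r$metric))
      next
    }
    nm <- if (!is.null(names(rates)) && nzchar(names(rates)[k])) names(rates)[k]
          else paste(r$unit, r$metric, sep = ".")
    out[[nm]] <- fc
  }
  if (length(skipped)) {
    warning("skipped series failing forecast preconditions: ",
            paste(skipped, collapse = ", "))
  }
  out
}

#' Flatten forecasts to an exportable table
#'
#' @param forecasts Output of [forecast_panel].
#' @return A data frame with columns `unit`, `metric`, `year`,
#'   `predicted_rate`, `intercept`, `slope`, `in_sample_rmse`,
#'   `clamped_flag`.
#' @export
forecasts_to_df <- function(forecasts) {
  if (length(forecasts) == 0L) {
    return(data.frame(unit = character(0), metric = character(0),
                      year = integer(0), predicted_rate = numeric(0),
                      intercept = numeric(0), slope = numeric(0),
                      in_sample_rmse = numeric(0), clamped_flag = logical(0)))
  }
  do.call(rbind, lapply(forecasts, function(fc) {
    data.frame(unit = fc$unit, metric = fc$metric,
               year = fc$predicted$year, predicted_rate = fc$predicted$rate,
               intercept = fc$intercept, slope = fc$slope,
               in_sample_rmse = fc$in_sample_rmse,
               clamped_flag = fc$predicted$clamped,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
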