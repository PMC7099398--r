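#' Centered moving average for an even period
#'
#' The standard 2-by-period centered moving average used to smooth a monthly
#' series before seasonal-index estimation: the average of the two adjacent
#' period-length windows, i.e. weights `(1/2, 1, ..., 1, 1/2) / period`. For
#' `period = 12` this aligns the smoother exactly on calendar months. The
#' first and last `period/2` entries are undefined (`NA`).
#'
#' @param values Numeric vector, length at least `period + 1`.
#' @param period Even integer smoothing period (12 for monthly data).
#' @return Numeric vector of the same length with `NA` at the undefined edges.
#' @examples
#' centered_moving_average(1:14, 12)  # exact on a linear series
#' @export
centered_moving_average <- function(values, period = 12L) {
  values <- as.numeric(values)
  period <- as.integer(period)
  if (period < 2L || period %% 2L != 0L) stop("period must be a positive even integer")
  if (length(values) < period + 1L) {
    stop(sprintf("series too short for a %d-term centered moving average (need >= %d points)",
                 period, period + 1L))
  }
  w <- c(0.5, rep(1, period - 1L), 0.5) / period
  as.numeric(stats::filter(values, w, sides = 2))
}

# Odd-length centered running mean; NA where the window does not fit.
odd_centered_mean <- function(values, window) {
  as.numeric(stats::filter(values, rep(1 / window, window), sides = 2))
}

monthly_means <- function(ratio, month) {
  vapply(1:12, function(m) {
    r <- ratio[month == m & is.finite(ratio)]
    if (length(r) == 0L) return(NA_real_)
    mean(r)
  }, numeric(1))
}

#' Seasonal indices by the monthly-average method
#'
#' Computes the ratio of the observed series to its centered moving average
#' wherever the latter is defined, averages the ratios by calendar month, and
#' rescales the twelve raw indices to mean exactly 1. The index for month m is
#' the multiplicative factor by which that month typically sits above or below
#' the smoothed level.
#'
#' @param values Observed series (positive numeric vector).
#' @param smoothed Output of [centered_moving_average] on `values` (`NA` at
#'   the edges).
#' @param month Calendar month (1-12) of each observation.
#' @return Numeric vector of 12 seasonal indices with mean exactly 1.
#' @export
seasonal_index <- function(values, smoothed, month) {
  values <- as.numeric(values)
  stopifnot(length(values) == length(smoothed), length(values) == length(month))
  defined <- !is.na(smoothed)
  if (any(smoothed[defined] == 0)) stop("smoothed series contains zeros; ratio undefined")
  ratio <- rep(NA_real_, length(values))
  ratio[defined] <- values[defined] / smoothed[defined]
  raw <- monthly_means(ratio, month)
  if (anyNA(raw)) {
    stop("calendar month(s) with no defined observed/smoothed ratio: ",
         paste(which(is.na(raw)), collapse = ", "))
  }
  raw / mean(raw)
}

# Precompute column-scaled QR decompositions of the polynomial design
# matrices for degrees 1..max_degree on time index t.
trend_design <- function(n, max_degree = 3L, t = seq_len(n)) {
  X <- cbind(1, t, t^2, t^3)[, seq_len(max_degree + 1L), drop = FALSE]
  scales <- apply(abs(X), 2, max)
  Xs <- sweep(X, 2, scales, "/")
  list(
    t = t, scales = scales,
    qrs = lapply(seq_len(max_degree), function(d) qr(Xs[, seq_len(d + 1L), drop = FALSE])),
    Xs = Xs
  )
}

fit_trend_pre <- function(y, pre, floor_eps = 1e-6) {
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  degrees <- seq_along(pre$qrs)
  cands <- vector("list", length(degrees))
  for (d in degrees) {
    k <- d + 1L
    cf_s <- qr.coef(pre$qrs[[d]], y)
    fitted <- drop(pre$Xs[, seq_len(k), drop = FALSE] %*% cf_s)
    rss <- sum((y - fitted)^2)
    adj <- if (tss < 1e-12 * n) NA_real_ else 1 - (rss / tss) * (n - 1) / (n - k)
    cands[[d]] <- list(degree = d,
                       coefficients = cf_s / pre$scales[seq_len(k)],
                       fitted = fitted, rss = rss, adj_r_squared = adj)
  }
  adjs <- vapply(cands, `[[`, numeric(1), "adj_r_squared")
  if (all(is.na(adjs))) {
    sel <- 1L  # constant series: degree-1 fit is the mean with slope ~0
  } else {
    best <- max(adjs, na.rm = TRUE)
    sel <- min(which(!is.na(adjs) & adjs >= best - 1e-9))
  }
  chosen <- cands[[sel]]
  names(chosen$coefficients) <- paste0("c", seq_len(sel + 1L) - 1L)
  list(
    fitted = pmax(chosen$fitted, floor_eps),
    model = list(
      family = "polynomial",
      degree = chosen$degree,
      coefficients = chosen$coefficients,
      adj_r_squared = chosen$adj_r_squared,
      candidates = data.frame(
        degree = degrees,
        adj_r_squared = adjs
      )
    )
  )
}

#' Fit the long-term trend curve
#'
#' Least-squares polynomial fits of degree 1, 2 and 3 of the (deseasonalized)
#' series on its time index; the returned model maximizes adjusted R-squared,
#' with ties (to within 1e-9) resolved toward the lowest degree. Fitted values
#' are floored at a small positive epsilon so the multiplicative model stays
#' defined.
#'
#' @param deseasonalized Positive numeric vector (at least 24 points).
#' @param t Time index (default `1..n`). Must not be constant.
#' @param floor_eps Positive floor applied to fitted values.
#' @return A list with `fitted` (numeric vector) and `model`: family, selected
#'   degree, coefficients on the raw time index, adjusted R-squared, and a
#'   `candidates` table with the adjusted R-squared of every degree tried.
#' @export
fit_trend <- function(deseasonalized, t = seq_along(deseasonalized), floor_eps = 1e-6) {
  y <- as.numeric(deseasonalized)
  if (length(y) < 24L) stop("need at least 24 points to fit a trend curve")
  if (length(t) != length(y)) stop("t and series must have equal length")
  if (length(unique(t)) < 2L) stop("degenerate design: all time points equal")
  fit_trend_pre(y, trend_design(length(y), t = as.numeric(t)), floor_eps = floor_eps)
}

#' Classical multiplicative decomposition of a monthly RSV series
#'
#' Decomposes an observed monthly series Y into long-term trend T, seasonal S,
#' cyclical C and irregular I under the multiplicative model
#' `Y(t) = T(t) * S(month(t)) * C(t) * I(t)`:
#'
#' 1. zeros in Y are replaced by 0.5 for ratio computations only (the
#'    multiplicative model is undefined at 0; 0.5 mirrors the `"<1"`
#'    suppression convention of the source scale);
#' 2. a 2x12 centered moving average smooths the series;
#' 3. seasonal indices come from the monthly-average method
#'    ([seasonal_index]);
#' 4. a polynomial trend curve is fitted to the deseasonalized series
#'    ([fit_trend]);
#' 5. the cyclical component is an odd centered moving average (13 months) of
#'    the trend- and season-adjusted ratio, set to 1 where the window is
#'    undefined at the edges;
#' 6. the irregular component is the residual ratio `Y / (T * S * C)`, so the
#'    reconstruction `T * S * C * I = Y` is exact wherever `Y > 0`.
#'
#' With `refine = TRUE` (default) steps 3-5 are iterated to their fixed point:
#' the seasonal indices are re-estimated as rescaled monthly means of
#' `Y / (T * C)` until convergence. On a noiseless multiplicative series the
#' generating components are an exact fixed point of this iteration, so known
#' seasonal indices are recovered to numerical precision; the one-pass
#' moving-average estimate (`refine = FALSE`) retains a small phase-dependent
#' leakage of the trend slope into the indices.
#'
#' @param series An [rsv_series] (length at least 36 months) or a positive
#'   numeric vector (months then assumed to start in January).
#' @param refine Iterate the seasonal/trend estimation to its fixed point
#'   (default) or perform the single-pass pipeline.
#' @param max_iter,tol Iteration cap and convergence tolerance on the maximum
#'   absolute change in the seasonal indices.
#' @param cycle_window Odd window (months) of the cyclical smoother.
#' @return An object of class `rsv_decomposition`: list with `unit`, `year`,
#'   `month`, `observed`, `smoothed`, `seasonal_indices` (12, mean exactly 1),
#'   `seasonal` (index applied per observation), `trend`, `cyclical`,
#'   `irregular`, `trend_model`, and `iterations` used.
#' @export
decompose_rsv <- function(series, refine = TRUE, max_iter = 40L, tol = 1e-11,
                          cycle_window = 13L) {
  if (is.numeric(series)) {
    n <- length(series)
    series <- rsv_series("series", 2004L + (seq_len(n) - 1L) %/% 12L,
                         (seq_len(n) - 1L) %% 12L + 1L, series)
  }
  stopifnot(inherits(series, "rsv_series"))
  if (cycle_window %% 2L != 1L) stop("cycle_window must be odd")
  y <- series$value
  n <- length(y)
  if (n < 36L) stop("need at least 36 months to decompose")
  if (all(y == 0)) stop("cannot decompose an all-zero series")
  month <- series$month
  yg <- ifelse(y == 0, 0.5, y)  # zero guard, ratios only

  smoothed <- centered_moving_average(yg, 12L)
  s <- seasonal_index(yg, smoothed, month)
  pre <- trend_design(n)
  iterations <- 0L

  if (refine) {
    for (it in seq_len(max_iter)) {
      tf <- fit_trend_pre(yg / s[month], pre)
      trend <- tf$fitted
      cyc <- odd_centered_mean(yg / (s[month] * trend), cycle_window)
      cyc[is.na(cyc)] <- 1
      s_new <- monthly_means(yg / (trend * cyc), month)
      s_new <- s_new / mean(s_new)
      delta <- max(abs(s_new - s))
      s <- s_new
      iterations <- it
      if (delta < tol) break
    }
  }

  tf <- fit_trend_pre(yg / s[month], pre)
  trend <- tf$fitted
  if (refine) {
    cyc <- odd_centered_mean(yg / (s[month] * trend), cycle_window)
  } else {
    cyc <- odd_centered_mean(smoothed / trend, cycle_window)
  }
  cyc[is.na(cyc)] <- 1
  irregular <- yg / (trend * s[month] * cyc)

  structure(list(
    unit = series$unit,
    year = series$year,
    month = month,
    observed = y,
    smoothed = smoothed,
    seasonal_indices = s,
    seasonal = s[month],
    trend = trend,
    cyclical = cyc,
    irregular = irregular,
    trend_model = tf$model,
    iterations = iterations
  ), class = "rsv_decomposition")
}

#' @export
print.rsv_decomposition <- function(x, ...) {
  cat(sprintf("<rsv_decomposition> %s: %d months; trend degree %d (adj R2 %.4f); seasonal range [%.3f, %.3f]\n",
              x$unit, length(x$observed), x$trend_model$degree,
              x$trend_model$adj_r_squared,
              min(x$seasonal_indices), max(x$seasonal_indices)))
  invisible(x)
}

#' @describeIn decompose_rsv Flatten a decomposition to a data frame with
#'   columns `month`, `observed`, `smoothed`, `seasonal_index_applied`,
#'   `trend`, `cyclical`, `irregular` (exportable via [write_table_csv]).
#' @param x An `rsv_decomposition`.
#' @param row.names,optional,... Ignored (S3 method compatibility).
#' @export
as.data.frame.rsv_decomposition <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    month = format_month_token(x$year, x$month),
    observed = x$observed,
    smoothed = x$smoothed,
    seasonal_index_applied = x$seasonal,
    trend = x$trend,
    cyclical = x$cyclical,
    irregular = x$irregular,
    stringsAsFactors = FALSE
  )
}

#' Serialize a fitted trend model to a key-value sidecar file
#'
#' Writes `key: value` lines (family, degree, coefficients on the raw time
#' index, adjusted R-squared of the selected model and of every candidate
#' degree) so a decomposition export is fully reproducible from text.
#'
#' @param model The `trend_model` element of an `rsv_decomposition` (or the
#'   `model` element of [fit_trend] output).
#' @param path Destination file path.
#' @return Invisibly, `path`.
#' @export
write_trend_model <- function(model, path) {
  lines <- c(
    paste0("family: ", model$family),
    paste0("degree: ", model$degree),
    paste0("coef_", seq_along(model$coefficients) - 1L, ": ",
           format_num(as.numeric(model$coefficients))),
    paste0("adj_r_squared: ", format_num(model$adj_r_squared)),
    paste0("candidate_degree_", model$candidates$degree, "_adj_r_squared: ",
           format_num(model$candidates$adj_r_squared))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
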