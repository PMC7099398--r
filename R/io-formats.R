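#' Monthly relative-search-volume series
#'
#' Container for one geographic unit's monthly search-volume series on the
#' Google-Trends 0-100 relative scale. Months must be consecutive (no gaps);
#' values are non-negative, and a freshly normalized series has maximum 100.
#' Values need not be integers: the continuous (unquantized) scale is used by
#' ground-truth recovery analyses, while files read from disk are always
#' integer-valued.
#'
#' @param unit Geographic label (state name or `"national"`).
#' @param year,month Integer vectors of equal length giving calendar year and
#'   1-based month for every observation, in order, with no missing months.
#' @param value Numeric vector of search volumes, same length, all `>= 0`.
#' @return An object of class `rsv_series`: a list with elements `unit`,
#'   `year`, `month`, `value`.
#' @examples
#' s <- rsv_series("Ohio", rep(2004, 3), 1:3, c(55, 100, 80))
#' length(s$value)
#' @export
rsv_series <- function(unit, year, month, value) {
  stopifnot(is.character(unit), length(unit) == 1L)
  year <- as.integer(year)
  month <- as.integer(month)
  value <- as.numeric(value)
  n <- length(value)
  if (n == 0L) stop("rsv_series must contain at least one observation")
  if (length(year) != n || length(month) != n) {
    stop("year, month and value must have equal length")
  }
  if (any(month < 1L | month > 12L)) stop("month must be in 1..12")
  idx <- year * 12L + (month - 1L)
  if (n > 1L && any(diff(idx) != 1L)) {
    stop("months must be strictly increasing and consecutive (no gaps)")
  }
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("values must be finite and non-negative")
  }
  structure(list(unit = unit, year = year, month = month, value = value),
            class = "rsv_series")
}

#' @export
print.rsv_series <- function(x, ...) {
  cat(sprintf("<rsv_series> %s: %d months (%04d-%02d to %04d-%02d), range [%g, %g]\n",
              x$unit, length(x$value), x$year[1], x$month[1],
              x$year[length(x$year)], x$month[length(x$month)],
              min(x$value), max(x$value)))
  invisible(x)
}

#' Annual age-adjusted rate series
#'
#' One unit's annual age-adjusted incidence or mortality rate per 100,000,
#' over consecutive calendar years.
#'
#' @param unit Geographic label.
#' @param metric `"incidence"` or `"mortality"`.
#' @param years Integer vector of consecutive calendar years.
#' @param rates Positive numeric vector, rate per 100,000, same length.
#' @return An object of class `rate_series`.
#' @export
rate_series <- function(unit, metric, years, rates) {
  stopifnot(is.character(unit), length(unit) == 1L)
  metric <- match.arg(metric, c("incidence", "mortality"))
  years <- as.integer(years)
  rates <- as.numeric(rates)
  if (length(years) == 0L) stop("rate_series must contain at least one year")
  if (length(years) != length(rates)) stop("years and rates must have equal length")
  if (length(years) > 1L && any(diff(years) != 1L)) {
    stop("years must be strictly increasing and consecutive")
  }
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("rates must be finite and strictly positive")
  }
  structure(list(unit = unit, metric = metric, years = years, rates = rates),
            class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf("<rate_series> %s %s: %d-%d, mean %.1f per 100,000\n",
              x$unit, x$metric, x$years[1], x$years[length(x$years)],
              mean(x$rates)))
  invisible(x)
}

# Round half away from zero (Google Trends displays integers; base round()
# is half-to-even).
round_half_up <- function(x) trunc(x + sign(x) * 0.5)

#' Normalize a raw search-volume series to the 0-100 relative scale
#'
#' Rescales so the period maximum maps to 100 and every other point is
#' proportional: `round(100 * raw / max(raw))`, rounding half away from zero,
#' clamped to `[0, 100]`. This reproduces the relative-search-volume scale in
#' which the maximum of a freshly normalized series is exactly 100.
#'
#' @param raw_values Numeric vector of non-negative search volumes, at least
#'   one of them positive.
#' @param quantize If `TRUE` (default), round to integers as Google Trends
#'   displays; if `FALSE`, return the continuous 0-100 rescaling (used when an
#'   exact multiplicative structure must be preserved).
#' @return Numeric vector on the 0-100 scale, same length and order, maximum
#'   exactly 100.
#' @examples
#' rsv_normalize(c(50, 25, 10))  # 100 50 20
#' rsv_normalize(c(3, 7, 9))     # 33 78 100
#' @export
rsv_normalize <- function(raw_values, quantize = TRUE) {
  x <- as.numeric(raw_values)
  if (length(x) == 0L) stop("cannot normalize an empty series")
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("raw values must be finite and non-negative")
  }
  mx <- max(x)
  if (mx <= 0) stop("cannot normalize an all-zero series")
  out <- 100 * x / mx
  if (quantize) out <- round_half_up(out)
  pmin(pmax(out, 0), 100)
}

format_month_token <- function(year, month) sprintf("%04d-%02d", year, month)

# Shortest decimal representation that round-trips through as.numeric().
format_num <- function(x) {
  vapply(x, function(xi) {
    if (is.na(xi)) return("NA")
    if (xi == floor(xi) && abs(xi) < 1e15) return(sprintf("%.0f", xi))
    for (d in 1:17) {
      s <- sprintf("%.*g", d, xi)
      if (as.numeric(s) == xi) return(s)
    }
    s
  }, character(1))
}

#' Read a monthly RSV series from CSV
#'
#' Expects the Google-Trends export dialect: one header line, then rows
#' `YYYY-MM,value` with integer values in `[0, 100]`. The suppressed-count
#' token `"<1"` is parsed as 0. Month gaps and malformed tokens are rejected
#' with an error naming the offending line.
#'
#' @param path File path.
#' @param unit Geographic label for the series. Default `NULL`: taken from
#'   the second header field when it is not the generic `"value"` (the
#'   [write_rsv_csv] convention, mirroring how Trends exports carry the
#'   geography in the header), else from the file name without directory,
#'   extension, or a leading `"rsv_"` prefix.
#' @return An [rsv_series].
#' @export
read_rsv_csv <- function(path, unit = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1L) stop("empty RSV file: ", path)
  if (is.null(unit)) {
    header_unit <- sub("^[^,]*,", "", lines[1])
    unit <- if (nzchar(header_unit) && !identical(header_unit, "value")) {
      header_unit
    } else {
      sub("^rsv_", "", sub("\\.[^.]*$", "", basename(path)))
    }
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) stop("RSV file has no data rows: ", path)
  years <- integer(length(body))
  months <- integer(length(body))
  values <- numeric(length(body))
  for (i in seq_along(body)) {
    lineno <- i + 1L
    parts <- strsplit(body[i], ",", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop(sprintf("line %d: expected 'YYYY-MM,value', got '%s'", lineno, body[i]))
    }
    tok <- trimws(parts[1])
    if (!grepl("^[0-9]{4}-(0[1-9]|1[0-2])$", tok)) {
      stop(sprintf("line %d: malformed month token '%s'", lineno, tok))
    }
    years[i] <- as.integer(substr(tok, 1, 4))
    months[i] <- as.integer(substr(tok, 6, 7))
    val <- trimws(parts[2])
    if (val == "<1") {
      values[i] <- 0
    } else if (grepl("^[0-9]+$", val)) {
      values[i] <- as.numeric(val)
      if (values[i] > 100) {
        stop(sprintf("line %d: value %s outside the 0-100 RSV scale", lineno, val))
      }
    } else {
      stop(sprintf("line %d: non-integer value '%s' (only '<1' is allowed)", lineno, val))
    }
  }
  idx <- years * 12L + (months - 1L)
  if (length(idx) > 1L) {
    bad <- which(diff(idx) != 1L)
    if (length(bad)) {
      stop(sprintf("line %d: gap or disorder in months after %s",
                   bad[1] + 2L, format_month_token(years[bad[1]], months[bad[1]])))
    }
  }
  rsv_series(unit, years, months, values)
}

#' Write a monthly RSV series to CSV
#'
#' Emits the same dialect [read_rsv_csv] consumes: a header whose second
#' field is the unit label, then `YYYY-MM,value` rows. Output is
#' locale-independent and byte-deterministic; a write/read round trip
#' reproduces the series (including its unit) exactly.
#'
#' @param series An [rsv_series].
#' @param path Destination file path.
#' @return Invisibly, `path`.
#' @export
write_rsv_csv <- function(series, path) {
  stopifnot(inherits(series, "rsv_series"))
  lines <- c(paste0("month,", series$unit),
             paste0(format_month_token(series$year, series$month), ",",
                    format_num(series$value)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read annual rate series from a long-format CSV
#'
#' Expects columns `unit,year,metric,rate` (header required), one row per
#' unit-year-metric. Duplicate keys and non-positive rates are rejected.
#'
#' @param path File path.
#' @return A list of [rate_series], one per (unit, metric) pair, named
#'   `"unit.metric"`, ordered by unit then metric.
#' @export
read_rates_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "integer", "character", "numeric"))
  if (!identical(names(df), c("unit", "year", "metric", "rate"))) {
    stop("rates CSV must have columns: unit, year, metric, rate")
  }
  if (nrow(df) == 0L) return(list())
  if (!all(df$metric %in% c("incidence", "mortality"))) {
    bad <- setdiff(unique(df$metric), c("incidence", "mortality"))
    stop("unknown metric label(s): ", paste(bad, collapse = ", "))
  }
  if (any(!is.finite(df$rate)) || any(df$rate <= 0)) {
    stop("rates must be finite and strictly positive")
  }
  key <- paste(df$unit, df$year, df$metric, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (unit, year, metric) rows: ",
         paste(utils::head(unique(key[duplicated(key)])), collapse = "; "))
  }
  df <- df[order(df$unit, df$metric, df$year), ]
  groups <- split(df, paste(df$unit, df$metric, sep = "."))
  out <- lapply(groups, function(g) rate_series(g$unit[1], g$metric[1], g$year, g$rate))
  out[order(names(out))]
}

#' Write annual rate series to a long-format CSV
#'
#' @param rates A list of [rate_series] (or a single one).
#' @param path Destination file path.
#' @return Invisibly, `path`.
#' @export
write_rates_csv <- function(rates, path) {
  if (inherits(rates, "rate_series")) rates <- list(rates)
  stopifnot(all(vapply(rates, inherits, logical(1), "rate_series")))
  rows <- unlist(lapply(rates, function(r) {
    paste0(r$unit, ",", r$years, ",", r$metric, ",", format_num(r$rates))
  }))
  writeLines(c("unit,year,metric,rate", rows), path, useBytes = TRUE)
  invisible(path)
}

#' Write a generic result table to CSV
#'
#' Deterministic, locale-independent CSV writer for result tables: period
#' decimal separator, UTF-8, stable column order, numeric columns formatted
#' with the shortest representation that round-trips through `as.numeric()`.
#'
#' @param rows A data frame.
#' @param path Destination file path.
#' @return Invisibly, `path`.
#' @export
write_table_csv <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  cols <- lapply(rows, function(col) {
    if (is.numeric(col) && !is.integer(col)) format_num(col)
    else if (is.logical(col) || is.integer(col)) as.character(col)
    else {
      col <- as.character(col)
      needs <- grepl('[",\n]', col)
      col[needs] <- paste0('"', gsub('"', '""', col[needs]), '"')
      col
    }
  })
  header <- paste(names(rows), collapse = ",")
  if (nrow(rows) == 0L) {
    writeLines(header, path, useBytes = TRUE)
    return(invisible(path))
  }
  body <- do.call(paste, c(cols, sep = ","))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}
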