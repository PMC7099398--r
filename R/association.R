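#' Merge annual disease rates with monthly search volumes
#'
#' Aligns each unit's annual incidence and mortality rates with its monthly
#' RSV series (original values and decomposed long-term trend), restricted to
#' the years for which rates exist (optionally further restricted by an
#' analysis window). Two alignment modes are provided:
#'
#' * `"monthly-replicate"` repeats each annual rate across that year's 12
#'   months, one row per month (the row accounting a 51-state, 12-year panel
#'   yields is 144 rows per state, 7344 in total);
#' * `"annual-aggregate"` averages the RSV (and trend) within each year and
#'   pairs one row per year, avoiding the 12-fold pseudo-replication of the
#'   annual rates.
#'
#' Units lacking the RSV series or either metric over the window are dropped
#' with a warning and recorded in the `dropped_units` attribute.
#'
#' @param rsv A list of [rsv_series] (or a single one).
#' @param trends Decomposed long-term trends aligned with `rsv`: a list (in
#'   the same order) of `rsv_decomposition` objects or numeric trend vectors,
#'   or `NULL` to fill the decomposed column with `NA`.
#' @param rates A list of [rate_series] covering both metrics per unit.
#' @param mode Alignment mode (see above).
#' @param start_year,end_year Optional analysis window (inclusive).
#' @return A data frame with columns `unit`, `year`, `month` (`NA` in
#'   annual-aggregate mode), `rsv_original`, `rsv_decomposed_trend`,
#'   `incidence_rate`, `mortality_rate`, `alignment_mode`, with attribute
#'   `dropped_units`.
#' @export
merge_rates_with_rsv <- function(rsv, trends, rates,
                                 mode = c("monthly-replicate", "annual-aggregate"),
                                 start_year = NULL, end_year = NULL) {
  mode <- match.arg(mode)
  if (inherits(rsv, "rsv_series")) rsv <- list(rsv)
  stopifnot(all(vapply(rsv, inherits, logical(1), "rsv_series")))
  if (!is.null(trends)) {
    if (length(trends) != length(rsv)) stop("trends must match rsv in length")
    trends <- lapply(trends, function(tr) {
      if (inherits(tr, "rsv_decomposition")) tr$trend else as.numeric(tr)
    })
  }
  stopifnot(all(vapply(rates, inherits, logical(1), "rate_series")))

  rate_lookup <- function(unit, metric) {
    hit <- vapply(rates, function(r) r$unit == unit && r$metric == metric, logical(1))
    if (sum(hit) > 1L) stop("conflicting duplicate rate series for ", unit, " ", metric)
    if (!any(hit)) return(NULL)
    rates[[which(hit)]]
  }

  pieces <- list()
  dropped <- character(0)
  for (k in seq_along(rsv)) {
    s <- rsv[[k]]
    tr <- if (is.null(trends)) rep(NA_real_, length(s$value)) else trends[[k]]
    if (length(tr) != length(s$value)) {
      stop("trend length mismatch for unit ", s$unit)
    }
    inc <- rate_lookup(s$unit, "incidence")
    mort <- rate_lookup(s$unit, "mortality")
    if (is.null(inc) || is.null(mort)) {
      dropped <- c(dropped, s$unit)
      next
    }
    years <- intersect(intersect(unique(s$year), inc$years), mort$years)
    if (!is.null(start_year)) years <- years[years >= start_year]
    if (!is.null(end_year)) years <- years[years <= end_year]
    # only complete 12-month years participate
    years <- years[vapply(years, function(y) sum(s$year == y) == 12L, logical(1))]
    if (length(years) == 0L) {
      dropped <- c(dropped, s$unit)
      next
    }
    keep <- s$year %in% years
    inc_rate <- inc$rates[match(s$year[keep], inc$years)]
    mort_rate <- mort$rates[match(s$year[keep], mort$years)]
    if (mode == "monthly-replicate") {
      pieces[[length(pieces) + 1L]] <- data.frame(
        unit = s$unit, year = s$year[keep], month = s$month[keep],
        rsv_original = s$value[keep], rsv_decomposed_trend = tr[keep],
        incidence_rate = inc_rate, mortality_rate = mort_rate,
        stringsAsFactors = FALSE
      )
    } else {
      yrs <- sort(years)
      agg <- function(v) vapply(yrs, function(y) mean(v[s$year[keep] == y]), numeric(1))
      pieces[[length(pieces) + 1L]] <- data.frame(
        unit = s$unit, year = yrs, month = NA_integer_,
        rsv_original = agg(s$value[keep]), rsv_decomposed_trend = agg(tr[keep]),
        incidence_rate = inc$rates[match(yrs, inc$years)],
        mortality_rate = mort$rates[match(yrs, mort$years)],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(dropped)) {
    warning("dropped unit(s) lacking rates or overlapping years: ",
            paste(dropped, collapse = ", "))
  }
  panel <- if (length(pieces)) do.call(rbind, pieces) else data.frame(
    unit = character(0), year = integer(0), month = integer(0),
    rsv_original = numeric(0), rsv_decomposed_trend = numeric(0),
    incidence_rate = numeric(0), mortality_rate = numeric(0)
  )
  panel$alignment_mode <- rep(mode, nrow(panel))
  attr(panel, "dropped_units") <- dropped
  panel
}

#' Spearman rank correlation with two-tailed t significance
#'
#' Ranks both vectors (average ranks for ties), takes the Pearson correlation
#' of the ranks, and computes a two-tailed p-value from the Student t
#' statistic `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of
#' freedom. `|rho| = 1` yields `p = 0` by convention. Optionally a two-sided
#' permutation p-value (on `|rho|`) is computed as a small-sample check; it
#' uses the current RNG state, so seed the caller for reproducibility.
#'
#' @param x,y Numeric vectors of equal length, `n >= 4`, neither constant.
#' @param n_perm Number of permutation resamples (0 = t approximation only).
#' @return A list with `rho`, `p_value`, `n`, and (when `n_perm > 0`)
#'   `p_permutation`.
#' @examples
#' spearman_rho(1:5, c(2, 4, 6, 8, 10))$rho  # 1
#' @export
spearman_rho <- function(x, y, n_perm = 0L) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4L) stop("need at least 4 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("Spearman correlation undefined for a constant vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  p <- if (1 - rho^2 <= 0) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  out <- list(rho = rho, p_value = p, n = n)
  if (n_perm > 0L) {
    perm <- vapply(seq_len(n_perm), function(i) {
      abs(stats::cor(rx, sample(ry)))
    }, numeric(1))
    out$p_permutation <- (1 + sum(perm >= abs(rho) - 1e-12)) / (n_perm + 1)
  }
  out
}

#' Per-state correlation of search volumes with disease rates
#'
#' Applies [spearman_rho] independently within each unit of a merged panel,
#' for every combination of RSV variant (original values vs decomposed
#' long-term trend) and metric (incidence, mortality). A unit whose rate or
#' RSV values are constant over the window (possible in short
#' annual-aggregate windows) is flagged undefined and excluded from the
#' significance counts. A Benjamini-Hochberg adjusted p-value over all
#' computed tests is emitted as a supplementary column; the `significant`
#' flag itself follows the per-state rule `p_value < alpha` with no
#' multiple-testing correction, matching how per-state counts are reported
#' in registry-vs-search studies.
#'
#' @param panel Output of [merge_rates_with_rsv].
#' @param alpha Significance level (default 0.05).
#' @param variants RSV variants to test (by default both, or only
#'   `"original"` when the panel has no decomposed column).
#' @return A data frame of class `correlation_results` with columns `unit`,
#'   `rsv_variant`, `metric`, `n`, `rho`, `p_value`, `significant`, `alpha`,
#'   `alignment_mode`, `bh_adjusted_p`. Undefined tests carry `NA` in `rho`,
#'   `p_value` and `significant`.
#' @export
correlate_states <- function(panel, alpha = 0.05,
                             variants = c("original", "decomposed")) {
  stopifnot(is.data.frame(panel), nrow(panel) > 0)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  variants <- match.arg(variants, several.ok = TRUE)
  varcol <- c(original = "rsv_original", decomposed = "rsv_decomposed_trend")
  metcol <- c(incidence = "incidence_rate", mortality = "mortality_rate")
  mode <- panel$alignment_mode[1]
  units <- unique(panel$unit)
  rows <- list()
  for (u in units) {
    sub <- panel[panel$unit == u, ]
    for (v in variants) {
      x <- sub[[varcol[[v]]]]
      for (m in names(metcol)) {
        y <- sub[[metcol[[m]]]]
        res <- if (length(x) < 4L || anyNA(x) ||
                   length(unique(x)) < 2L || length(unique(y)) < 2L) {
          list(rho = NA_real_, p_value = NA_real_, n = length(x))
        } else {
          spearman_rho(x, y)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          unit = u, rsv_variant = v, metric = m, n = res$n,
          rho = res$rho, p_value = res$p_value,
          significant = if (is.na(res$p_value)) NA else res$p_value < alpha,
          alpha = alpha, alignment_mode = mode,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out$bh_adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  class(out) <- c("correlation_results", "data.frame")
  out
}

#' Summarize significant-state counts per pairing
#'
#' Counts, for each (RSV variant, metric) pairing, how many units are flagged
#' significant, and lists the non-significant units (the form in which
#' state-level search-surveillance results are reported). Undefined units are
#' counted separately so that
#' `n_significant + length(non-significant) + n_undefined = n_total`.
#'
#' @param results Output of [correlate_states].
#' @return A data frame with one row per pairing: `rsv_variant`, `metric`,
#'   `alignment_mode`, `n_significant`, `n_total`, `n_undefined`,
#'   `non_significant_units` (semicolon-joined).
#' @export
summarize_correlations <- function(results) {
  stopifnot(inherits(results, "correlation_results") || is.data.frame(results))
  pairings <- unique(results[, c("rsv_variant", "metric", "alignment_mode")])
  rows <- lapply(seq_len(nrow(pairings)), function(i) {
    sub <- results[results$rsv_variant == pairings$rsv_variant[i] &
                     results$metric == pairings$metric[i] &
                     results$alignment_mode == pairings$alignment_mode[i], ]
    nonsig <- sub$unit[!is.na(sub$significant) & !sub$significant]
    data.frame(
      rsv_variant = pairings$rsv_variant[i],
      metric = pairings$metric[i],
      alignment_mode = pairings$alignment_mode[i],
      n_significant = sum(sub$significant, na.rm = TRUE),
      n_total = nrow(sub),
      n_undefined = sum(is.na(sub$significant)),
      non_significant_units = paste(sort(nonsig), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
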