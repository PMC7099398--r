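make_small_panel <- function(cfg, mode = "monthly-replicate") {
  p <- simulate_panel(cfg)
  dec <- lapply(p$rsv, decompose_rsv)
  merge_rates_with_rsv(p$rsv, dec, p$rates, mode = mode)
}

test_that("monthly-replicate merge accounts 12 rows per unit-year", {
  cfg <- quick_config(n_states = 3, seed = 701)
  panel <- make_small_panel(cfg)
  expect_equal(nrow(panel), 3 * 12 * 12)
  expect_equal(as.vector(table(panel$unit)), rep(144L, 3))
  # every row's annual rate equals the source value for that unit-year
  p <- simulate_panel(cfg)
  for (u in names(p$rsv)) {
    src <- p$rates[[paste0(u, ".incidence")]]
    sub <- panel[panel$unit == u, ]
    expect_identical(sub$incidence_rate, src$rates[match(sub$year, src$years)])
  }
})

test_that("one unit, one year gives 12 or 1 rows depending on mode", {
  s <- rsv_series("Maine", rep(2004, 12), 1:12, rsv_normalize(20 + 1:12))
  rl <- list(rate_series("Maine", "incidence", 2004, 55),
             rate_series("Maine", "mortality", 2004, 41))
  pm <- merge_rates_with_rsv(list(s), list(seq(1, 2, length.out = 12)), rl,
                             mode = "monthly-replicate")
  pa <- merge_rates_with_rsv(list(s), list(seq(1, 2, length.out = 12)), rl,
                             mode = "annual-aggregate")
  expect_equal(nrow(pm), 12L)
  expect_equal(nrow(pa), 1L)
  expect_true(is.na(pa$month))
})

test_that("annual-aggregate values equal hand-computed 12-month means", {
  cfg <- quick_config(n_states = 2, seed = 702)
  p <- simulate_panel(cfg)
  dec <- lapply(p$rsv, decompose_rsv)
  pa <- merge_rates_with_rsv(p$rsv, dec, p$rates, mode = "annual-aggregate")
  for (u in names(p$rsv)) {
    s <- p$rsv[[u]]
    for (y in 2004:2015) {
      expect_equal(pa$rsv_original[pa$unit == u & pa$year == y],
                   mean(s$value[s$year == y]))
    }
  }
})

test_that("units lacking a metric are dropped with a warning record", {
  cfg <- quick_config(n_states = 2, seed = 703)
  p <- simulate_panel(cfg)
  rates <- p$rates[!grepl("^Alaska\\.mortality$", names(p$rates))]
  expect_warning(
    panel <- merge_rates_with_rsv(p$rsv, NULL, rates, mode = "monthly-replicate"),
    "Alaska"
  )
  expect_equal(attr(panel, "dropped_units"), "Alaska")
  expect_equal(unique(panel$unit), "Alabama")
})

test_that("spearman_rho handles the monotone limits", {
  expect_equal(spearman_rho(1:5, c(2, 4, 6, 8, 10)),
               list(rho = 1, p_value = 0, n = 5L))
  expect_equal(spearman_rho(1:5, c(10, 8, 6, 4, 2))$rho, -1)
  expect_equal(spearman_rho(1:5, c(10, 8, 6, 4, 2))$p_value, 0)
  expect_error(spearman_rho(1:3, 1:3), "4")
  expect_error(spearman_rho(1:5, rep(2, 5)), "constant")
})

test_that("spearman_rho matches the brute-force rank-then-Pearson oracle", {
  set.seed(704)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    x <- sample(1:6, n, replace = TRUE) + stats::rnorm(n, 0, 0.01 * (i %% 2))
    y <- sample(1:6, n, replace = TRUE) + stats::rnorm(n, 0, 0.01 * ((i + 1) %% 2))
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    got <- spearman_rho(x, y)
    want <- oracle_spearman(x, y)
    expect_equal(got$rho, want$rho, tolerance = 1e-12)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
  }
})

test_that("spearman_rho is invariant to strictly monotone transforms", {
  set.seed(705)
  x <- stats::runif(20, 1, 100)
  y <- stats::runif(20, 20, 80)
  base <- spearman_rho(x, y)
  expect_equal(spearman_rho(exp(x / 50), y^3)$rho, base$rho, tolerance = 1e-14)
  expect_equal(spearman_rho(log(x), sqrt(y))$p_value, base$p_value,
               tolerance = 1e-12)
})

test_that("permutation p-value is calibrated against the t approximation", {
  set.seed(706)
  x <- stats::runif(12); y <- stats::runif(12)
  got <- spearman_rho(x, y, n_perm = 2000)
  expect_true(got$p_permutation > 0 && got$p_permutation <= 1)
  expect_lt(abs(got$p_permutation - got$p_value), 0.12)
})

test_that("correlate_states equals per-unit spearman_rho with no pooling", {
  cfg <- quick_config(n_states = 4, seed = 707)
  panel <- make_small_panel(cfg, mode = "annual-aggregate")
  res <- correlate_states(panel, alpha = 0.05)
  expect_equal(nrow(res), 4 * 2 * 2)
  for (i in seq_len(nrow(res))) {
    sub <- panel[panel$unit == res$unit[i], ]
    xcol <- if (res$rsv_variant[i] == "original") "rsv_original" else "rsv_decomposed_trend"
    ycol <- paste0(res$metric[i], "_rate")
    want <- spearman_rho(sub[[xcol]], sub[[ycol]])
    expect_equal(res$rho[i], want$rho)
    expect_equal(res$p_value[i], want$p_value)
    expect_identical(res$significant[i], want$p_value < 0.05)
  }
})

test_that("undefined units (constant rates) are flagged and counts conserve", {
  s <- simulate_rsv_series(quick_config(n_states = 1, seed = 708), 1)
  d <- decompose_rsv(s)
  rl <- list(rate_series("Alabama", "incidence", 2004:2015, rep(50, 12)),
             rate_series("Alabama", "mortality", 2004:2015, 40 + 1:12))
  panel <- merge_rates_with_rsv(list(s), list(d), rl, mode = "annual-aggregate")
  res <- correlate_states(panel)
  inc <- res[res$metric == "incidence", ]
  expect_true(all(is.na(inc$rho)) && all(is.na(inc$significant)))
  sm <- summarize_correlations(res)
  expect_true(all(sm$n_significant +
                    ifelse(nzchar(sm$non_significant_units),
                           lengths(strsplit(sm$non_significant_units, ";")), 0L) +
                    sm$n_undefined == sm$n_total))
})

test_that("a mixed linked/null panel recovers every linked unit", {
  linked_cfg <- quick_config(n_states = 30, seed = 709,
                             rate_link_strength = 0.95, irregular_sd = 0.02)
  null_cfg <- quick_config(n_states = 21, seed = 710, rate_link_strength = 0)
  linked <- simulate_panel(linked_cfg)
  null <- simulate_panel(null_cfg)
  # relabel the null units so the two sub-panels do not collide
  null$rsv <- lapply(null$rsv, function(s) { s$unit <- paste0(s$unit, " (null)"); s })
  null$rates <- lapply(null$rates, function(r) { r$unit <- paste0(r$unit, " (null)"); r })
  rsv <- c(linked$rsv, null$rsv)
  rates <- c(linked$rates, null$rates)
  dec <- lapply(rsv, decompose_rsv)
  panel <- merge_rates_with_rsv(rsv, dec, rates, mode = "annual-aggregate")
  res <- correlate_states(panel)
  dec_inc <- res[res$rsv_variant == "decomposed" & res$metric == "incidence", ]
  linked_rows <- dec_inc[!grepl("\\(null\\)$", dec_inc$unit), ]
  expect_true(all(linked_rows$significant))
  expect_gte(sum(dec_inc$significant), 30)
  # oracle: counting equals independent per-unit application
  manual <- vapply(split(panel, panel$unit), function(sub) {
    spearman_rho(sub$rsv_decomposed_trend, sub$incidence_rate)$p_value < 0.05
  }, logical(1))
  expect_equal(sum(dec_inc$significant), sum(manual))
})

test_that("modes agree when the RSV is constant within each year", {
  values <- rsv_normalize(rep(c(30, 40, 55, 70, 85, 100, 90, 75, 60, 45, 35, 31),
                              each = 12))
  s <- rsv_series("Utah", rep(2004:2015, each = 12), rep(1:12, 12), values)
  set.seed(711)
  rl <- list(rate_series("Utah", "incidence", 2004:2015, stats::runif(12, 40, 60)),
             rate_series("Utah", "mortality", 2004:2015, stats::runif(12, 30, 50)))
  tr <- rep(1, 144)
  pm <- merge_rates_with_rsv(list(s), list(tr), rl, mode = "monthly-replicate")
  pa <- merge_rates_with_rsv(list(s), list(tr), rl, mode = "annual-aggregate")
  rm_ <- correlate_states(pm, variants = "original")
  ra <- correlate_states(pa, variants = "original")
  expect_equal(rm_$rho, ra$rho, tolerance = 1e-12)
})
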