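test_that("centered moving average is exact on constants and linear series", {
  expect_equal(centered_moving_average(rep(7, 30), 12)[7:24], rep(7, 18))
  tt <- 1:40
  lin <- 3 + 0.25 * tt
  got <- centered_moving_average(lin, 12)
  expect_equal(got[7:34], lin[7:34])
  expect_true(all(is.na(got[1:6])) && all(is.na(got[35:40])))
})

test_that("centered moving average matches brute-force window sums", {
  set.seed(501)
  x <- stats::runif(14, 1, 100)
  got <- centered_moving_average(x, 12)
  want <- oracle_cma(x, 12)
  expect_equal(which(!is.na(got)), c(7L, 8L))
  expect_equal(got, want, tolerance = 1e-12)
  # longer noisy series too
  x <- stats::runif(60, 1, 100)
  expect_equal(centered_moving_average(x, 12), oracle_cma(x, 12), tolerance = 1e-12)
})

test_that("centered moving average validates its preconditions", {
  expect_error(centered_moving_average(1:12, 12), "short")
  expect_error(centered_moving_average(1:30, 11), "even")
})

test_that("seasonal indices: deseasonalized input gives all ones, mean exactly 1", {
  x <- rep(50, 48)
  sm <- centered_moving_average(x, 12)
  month <- rep(1:12, 4)
  expect_equal(seasonal_index(x, sm, month), rep(1, 12), tolerance = 1e-9)
  # rescaling contract on arbitrary ratios
  set.seed(502)
  for (i in 1:20) {
    y <- stats::runif(48, 10, 90)
    idx <- seasonal_index(y, centered_moving_average(y, 12), month)
    expect_equal(mean(idx), 1, tolerance = 1e-14)
  }
})

test_that("seasonal_index errors when a calendar month has no defined ratio", {
  x <- stats::runif(14, 1, 10)
  sm <- centered_moving_average(x, 12)
  month <- ((0:13) %% 12) + 1
  expect_error(seasonal_index(x, sm, month), "no defined")
})

test_that("fit_trend recovers exact polynomials and picks the lowest adequate degree", {
  tt <- 1:48
  lin <- fit_trend(10 + 0.5 * tt)
  expect_equal(lin$model$degree, 1L)
  expect_equal(unname(lin$model$coefficients), c(10, 0.5), tolerance = 1e-9)
  expect_equal(lin$fitted, 10 + 0.5 * tt, tolerance = 1e-9)

  quad <- fit_trend(100 - 2 * tt + 0.05 * tt^2)
  expect_gte(quad$model$degree, 2L)
  expect_equal(quad$fitted, 100 - 2 * tt + 0.05 * tt^2, tolerance = 1e-9)
  expect_equal(nrow(quad$model$candidates), 3L)
})

test_that("fit_trend agrees with an independent normal-equations solve", {
  set.seed(503)
  tt <- 1:144
  y <- 60 - 0.12 * tt + stats::rnorm(144, 0, 2)
  fit <- fit_trend(y)
  X <- cbind(1, tt, tt^2, tt^3)[, seq_len(fit$model$degree + 1), drop = FALSE]
  beta <- oracle_ols(X, y)
  expect_equal(unname(fit$model$coefficients), unname(beta), tolerance = 1e-8)
  expect_lt(fit$model$coefficients[["c1"]], 0)  # slope sign recovered
  expect_error(fit_trend(y, t = rep(1, 144)), "degenerate")
})

test_that("decompose recovers known seasonal indices on noiseless ground truth", {
  idx <- default_seasonal_indices()
  s <- simulate_rsv_series(noiseless_config(seed = 601), 1, quantize = FALSE)
  d <- decompose_rsv(s)
  expect_equal(d$seasonal_indices, idx, tolerance = 1e-6)
  expect_lt(d$trend_model$coefficients[["c1"]], 0)  # monotone direction exact
  # one-pass (unrefined) estimate retains the slope-phase leakage
  d0 <- decompose_rsv(s, refine = FALSE)
  expect_gt(max(abs(d0$seasonal_indices - idx)), 1e-6)
  expect_equal(d0$seasonal_indices, idx, tolerance = 1e-2)
})

test_that("integer quantization caps recovery at rounding precision", {
  idx <- default_seasonal_indices()
  s <- simulate_rsv_series(noiseless_config(seed = 602), 1, quantize = TRUE)
  d <- decompose_rsv(s)
  expect_equal(d$seasonal_indices, idx, tolerance = 2e-2)
})

test_that("reconstruction T*S*C*I = Y holds wherever defined", {
  s <- simulate_rsv_series(quick_config(n_states = 1, seed = 603), 1)
  d <- decompose_rsv(s)
  recon <- d$trend * d$seasonal * d$cyclical * d$irregular
  pos <- d$observed > 0
  expect_lt(max(abs(recon[pos] - d$observed[pos]) / d$observed[pos]), 1e-9)
  expect_true(all(d$trend > 0))
  expect_equal(mean(d$seasonal_indices), 1, tolerance = 1e-9)
})

test_that("constant series decomposes to unit components", {
  d <- decompose_rsv(rep(80, 48))
  expect_equal(d$seasonal_indices, rep(1, 12), tolerance = 1e-9)
  expect_equal(d$trend, rep(80, 48), tolerance = 1e-9)
  expect_equal(d$cyclical, rep(1, 48), tolerance = 1e-9)
  expect_equal(d$irregular, rep(1, 48), tolerance = 1e-9)
})

test_that("decomposition is invariant to positive rescaling of the input", {
  set.seed(604)
  y <- (70 - 0.1 * (1:144)) * rep(default_seasonal_indices(), 12) *
    exp(stats::rnorm(144, 0, 0.04))
  d1 <- decompose_rsv(y)
  d2 <- decompose_rsv(3.7 * y)
  expect_equal(d1$seasonal_indices, d2$seasonal_indices, tolerance = 1e-9)
  expect_equal(d2$trend / d1$trend, rep(3.7, 144), tolerance = 1e-8)
})

test_that("a 2004-2018 series decomposes into components of length 180", {
  cfg <- panel_config(n_states = 1, start_year = 2004, end_year = 2018, seed = 605)
  d <- decompose_rsv(simulate_rsv_series(cfg, 1))
  expect_length(d$trend, 180L)
  expect_length(d$irregular, 180L)
})

test_that("decompose guards its preconditions and zero observations", {
  expect_error(decompose_rsv(rep(10, 20)), "36")
  expect_error(decompose_rsv(rep(0, 48)), "all-zero")
  y <- rep(c(0, 40, 60, 80), 12)  # zeros guarded as 0.5, observed unchanged
  d <- decompose_rsv(y)
  expect_equal(d$observed[1], 0)
  expect_true(all(is.finite(d$irregular)))
})

test_that("decomposition exports to the documented table and sidecar", {
  s <- simulate_rsv_series(quick_config(n_states = 1, seed = 606), 1)
  d <- decompose_rsv(s)
  df <- as.data.frame(d)
  expect_named(df, c("month", "observed", "smoothed", "seasonal_index_applied",
                     "trend", "cyclical", "irregular"))
  expect_equal(nrow(df), 144L)
  expect_equal(df$month[1], "2004-01")
  path <- withr::local_tempfile(fileext = ".txt")
  write_trend_model(d$trend_model, path)
  lines <- readLines(path)
  expect_true(any(grepl("^family: polynomial$", lines)))
  expect_true(any(grepl("^degree: ", lines)))
  expect_true(any(grepl("^candidate_degree_3_adj_r_squared: ", lines)))
})
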