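# Independent brute-force oracles, deliberately written without reusing the
# package's code paths (or base shortcuts like rank()/cor()).

# Average ranks by counting comparisons.
oracle_rank <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, numeric(1))
}

# Pearson correlation from explicit sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Spearman rho + two-tailed t p-value, rank-then-Pearson route.
oracle_spearman <- function(x, y) {
  rho <- oracle_pearson(oracle_rank(x), oracle_rank(y))
  n <- length(x)
  p <- if (1 - rho^2 <= 0) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p)
}

# 2 x period centered moving average by explicit window sums.
oracle_cma <- function(x, period = 12L) {
  n <- length(x)
  half <- period / 2
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - half < 1 || i + half > n) next
    w1 <- mean(x[(i - half):(i + half - 1)])
    w2 <- mean(x[(i - half + 1):(i + half)])
    out[i] <- (w1 + w2) / 2
  }
  out
}

# OLS by explicit normal equations.
oracle_ols <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}
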