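# Shared fixtures and independent oracles for the test suite.

# Random two-instance dataset with structured outcomes: per-condition linear
# models with independent noise, so interaction structure is present but not
# degenerate.
rand_fixture <- function(n = 25, m = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- as.data.frame(matrix(stats::rnorm(n * m), n))
  names(w) <- paste0("W", seq_len(m))
  b1 <- stats::rnorm(m + 1)
  b2 <- stats::rnorm(m + 1)
  X <- cbind(1, as.matrix(w))
  y1 <- drop(X %*% b1) + stats::rnorm(n)
  y2 <- drop(X %*% b2) + stats::rnorm(n)
  wide_data(y1, y2, w)
}

# Brute-force normal-equations least squares: the independent oracle for the
# QR-based engine.
ne_solve <- function(X, y) {
  xtx <- t(X) %*% X
  b <- solve(xtx, t(X) %*% y)
  res <- y - X %*% b
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  list(b = drop(b), Sigma = sigma2 * solve(xtx), sigma2 = sigma2, df = df)
}

# Write a small wide-form CSV and return its path.
write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

# Brute-force Johnson-Neyman oracle: scan |t(W)| - t_crit on a fine grid over
# the observed range and report midpoints of the sign changes.
jn_grid_oracle <- function(fit, w, alpha = 0.05, grid_n = 1e5) {
  tcrit <- critical_t(alpha, fit$df)
  grid <- seq(min(w), max(w), length.out = grid_n)
  est <- fit$b[1] + fit$b[2] * grid
  v <- fit$Sigma[1, 1] + grid^2 * fit$Sigma[2, 2] + 2 * grid * fit$Sigma[1, 2]
  s <- abs(est / sqrt(v)) - tcrit
  idx <- which(s[-1] * s[-length(s)] < 0)
  (grid[idx] + grid[idx + 1]) / 2
}
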