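test_that("design matrices have the documented term structure", {
  d2 <- rand_fixture(n = 20, m = 2, seed = 1)
  X_add <- build_design(d2, mod_spec("additive"))
  expect_equal(colnames(X_add), c("constant", "W1", "W2"))

  X_mul <- build_design(d2, mod_spec("multiplicative"))
  expect_equal(colnames(X_mul), c("constant", "W1", "W2", "W1*W2"))
  expect_equal(X_mul[, "W1*W2"], X_mul[, "W1"] * X_mul[, "W2"],
               ignore_attr = TRUE)

  d1 <- rand_fixture(n = 20, m = 1, seed = 2)
  expect_equal(ncol(build_design(d1, mod_spec("additive"))), 2L)
  expect_equal(ncol(build_design(d1, mod_spec("multiplicative"))), 2L)

  d3 <- rand_fixture(n = 20, m = 3, seed = 3)
  X3 <- build_design(d3, mod_spec("multiplicative"))
  expect_equal(ncol(X3), 8L)  # 2^3 subsets including intercept
  # subset-size-then-input order
  expect_equal(colnames(X3),
               c("constant", "W1", "W2", "W3", "W1*W2", "W1*W3", "W2*W3",
                 "W1*W2*W3"))

  # duplicated column -> singular-design error naming the culprit
  dd <- wide_data(rnorm(10), rnorm(10),
                  data.frame(W1 = 1:10, W2 = 2 * (1:10)))
  expect_error(build_design(dd, mod_spec("additive")), "W2")
})

test_that("OLS engine reproduces the hand-solved fixture", {
  # centered slope fixture solved by hand via the normal equations
  X <- cbind(constant = 1, W = c(-1.5, -0.5, 0.5, 1.5))
  y <- c(0, 1, 2, 4)
  f <- ols_fit(y, X)
  expect_equal(unname(f$b), c(1.75, 1.30))
  expect_equal(f$df, 2L)
  expect_equal(f$sigma2, 0.15)
  expect_equal(unname(f$Sigma[2, 2]), 0.03)
  expect_equal(unname(f$Sigma[1, 1]), 0.0375)

  # the same numbers from the independent normal-equations oracle
  o <- ne_solve(X, y)
  expect_equal(unname(f$b), unname(o$b), tolerance = 1e-12)
  expect_equal(unname(f$Sigma), unname(o$Sigma), tolerance = 1e-12)
})

test_that("OLS engine matches independent solvers on random designs", {
  set.seed(20)
  for (rep in 1:25) {
    n <- sample(8:30, 1)
    q <- sample(1:4, 1)
    X <- cbind(1, matrix(rnorm(n * q), n))
    colnames(X) <- c("constant", paste0("W", 1:q))
    y <- rnorm(n)
    f <- ols_fit(y, X)
    o <- ne_solve(X, y)
    expect_equal(unname(f$b), unname(o$b), tolerance = 1e-8)
    expect_equal(unname(f$Sigma), unname(o$Sigma), tolerance = 1e-8)
    lmf <- lm(y ~ X[, -1])
    expect_equal(unname(f$b), unname(coef(lmf)), tolerance = 1e-8)
    expect_equal(unname(f$Sigma), unname(vcov(lmf)), tolerance = 1e-8)
    expect_equal(f$r2, summary(lmf)$r.squared, tolerance = 1e-8)
  }
})

test_that("degenerate responses and designs are handled", {
  X <- cbind(constant = rep(1, 6), W = rnorm(6))
  yc <- rep(2.5, 6)
  f <- ols_fit(yc, X)
  expect_equal(unname(f$b), c(2.5, 0), tolerance = 1e-12)
  expect_true(is.na(f$r2))  # R^2 undefined for a constant response

  # intercept-only model: closed form
  y <- c(1, 3, 2, 6, 4)
  f0 <- ols_fit(y, matrix(1, 5, 1, dimnames = list(NULL, "constant")))
  expect_equal(unname(f0$b), mean(y))
  expect_equal(unname(f0$Sigma[1, 1]), var(y) / 5)
})

test_that("difference-model coefficients equal per-condition differences", {
  set.seed(31)
  for (m in 1:2) {
    for (model in c("additive", "multiplicative")) {
      d <- rand_fixture(n = 30, m = m)
      spec <- mod_spec(model)
      fd <- fit_difference_model(d, spec)
      fc <- fit_per_condition(d, spec)
      expect_equal(unname(fd$b), unname(fc$fit1$b - fc$fit2$b),
                   tolerance = 1e-10)
    }
  }
  # identical instances: per-condition fits coincide, difference slopes zero
  y <- rnorm(15)
  w <- data.frame(W1 = rnorm(15))
  d0 <- wide_data(y, y, w)
  fc0 <- fit_per_condition(d0)
  expect_equal(fc0$fit1$b, fc0$fit2$b, tolerance = 1e-12)
  fd0 <- fit_difference_model(d0)
  expect_equal(unname(fd0$b), c(0, 0), tolerance = 1e-12)
})

test_that("single centered moderator gives orthogonal intercept and slope", {
  d <- rand_fixture(n = 40, m = 1, seed = 5)
  f <- fit_difference_model(d, mod_spec(center = TRUE))
  expect_lt(abs(f$Sigma[1, 2]), 1e-12 * f$Sigma[1, 1])
  # and the overall F equals the squared slope t
  expect_equal(f$F$statistic, f$table$t[2]^2, tolerance = 1e-10)
})

test_that("coefficient recovery is unbiased across a small parameter grid", {
  reps <- 300
  for (n in c(30, 100)) {
    for (rho in c(0, 0.5)) {
      est <- matrix(NA_real_, reps, 2)
      for (r in seq_len(reps)) {
        d <- generate_two_instance(n, b_cond1 = c(1, 0.3),
                                   b_cond2 = c(1.5, -0.2),
                                   sigma1 = 1, sigma2 = 2, rho = rho,
                                   seed = 5000 + 17 * r + n + round(100 * rho))
        d2 <- wide_data(d$y2, d$y1, d$w, y_names = c("y2", "y1"))
        est[r, ] <- fit_difference_model(d2, mod_spec(center = FALSE))$b
      }
      truth <- c(0.5, -0.5)  # b_cond2 - b_cond1
      mc_se <- apply(est, 2, sd) / sqrt(reps)
      expect_true(all(abs(colMeans(est) - truth) < 3 * mc_se + 1e-12))
    }
  }
})
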