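test_that("CSV ingestion applies listwise deletion and records the count", {
  df <- data.frame(pre = c(4, 3, 5, 2, 4, 3),
                   post = c(3, NA, 4, 2, 3, 1),
                   inflame = c(-1, 0.5, 0, 1, -0.5, 2))
  path <- write_fixture_csv(df)
  d <- read_wide_csv(path, y = c("pre", "post"), w = "inflame")
  expect_s3_class(d, "wide_data")
  expect_equal(d$n, 5L)
  expect_equal(d$n_dropped, 1L)
  expect_equal(d$n + d$n_dropped, nrow(df))
  expect_equal(d$y_names, c("pre", "post"))

  expect_error(read_wide_csv(path, y = c("pre", "nope"), w = "inflame"),
               "nope")
  # moderator entirely missing -> every row dropped -> sample-size error
  df2 <- df
  df2$inflame <- NA_real_
  expect_error(read_wide_csv(write_fixture_csv(df2), y = c("pre", "post"),
                             w = "inflame"),
               "too few complete rows")
})

test_that("difference score is first-listed minus second-listed", {
  d <- wide_data(c(3, 5), c(1, 2), data.frame(W = c(0, 1)))
  expect_equal(make_difference(d), c(2, 3))

  # identical instances -> identically zero difference
  y <- rnorm(10)
  d0 <- wide_data(y, y, data.frame(W = rnorm(10)))
  expect_equal(make_difference(d0), rep(0, 10))

  # with outcomes listed (pre, post), positive difference = drop after
  # treatment
  d2 <- wide_data(c(5, 4), c(2, 4), data.frame(W = c(0, 1)),
                  y_names = c("pre", "post"))
  expect_true(make_difference(d2)[1] > 0)
})

test_that("mean-centering zeroes the sample mean and stores the original", {
  d <- wide_data(1:3, 3:1, data.frame(W = c(1, 2, 3)))
  dc <- center_moderators(d)
  expect_equal(dc$w$W, c(-1, 0, 1))
  expect_equal(unname(dc$w_means["W"]), 2)
  expect_true(dc$centered["W"])

  # idempotent on an already-centered column
  dcc <- center_moderators(dc)
  expect_equal(dcc$w$W, dc$w$W)

  d3 <- wide_data(rnorm(5), rnorm(5),
                  data.frame(W = c(-1.5, -0.5, 0.5, 1.5, 0)))
  d3c <- center_moderators(d3)
  expect_lt(abs(mean(d3c$w$W)), 1e-12)

  # explicit request to center a categorical column is an error; the scalar
  # default skips it
  d4 <- wide_data(rnorm(6), rnorm(6),
                  data.frame(W = rnorm(6), G = rep(c("a", "b", "c"), 2)))
  expect_error(center_moderators(d4, center = c(TRUE, TRUE)), "categorical")
  d4c <- center_moderators(d4, center = TRUE)
  expect_lt(abs(mean(d4c$w$W)), 1e-12)
  expect_false(d4c$centered["G"])

  # numeric 0/1 dichotomy is left on its original scale
  d5 <- wide_data(rnorm(6), rnorm(6), data.frame(G = rep(0:1, 3)))
  expect_equal(center_moderators(d5)$w$G, rep(0:1, 3))
})

test_that("multicategorical coding produces k-1 well-formed columns", {
  therapy <- c("ACT", "AR", "ACT", "AR")
  ind <- encode_multicategorical(therapy, "indicator")
  expect_equal(ncol(ind), 1L)
  expect_equal(unname(ind[, 1]), c(0, 1, 0, 1))  # ACT (first sorted) = 0

  g3 <- c("a", "b", "c", "a", "b", "c")
  ind3 <- encode_multicategorical(g3, "indicator")
  expect_equal(ncol(ind3), 2L)
  expect_equal(unname(ind3[1, ]), c(0, 0))  # reference row all-zero

  h3 <- encode_multicategorical(g3, "helmert")
  expect_equal(ncol(h3), 2L)
  expect_equal(unname(colSums(h3[1:3, ])), c(0, 0))  # each contrast sums to 0
  expect_equal(unname(h3[1:3, 1]), c(-1, 1, 0))
  expect_equal(unname(h3[1:3, 2]), c(-1, -1, 2))

  expect_error(encode_multicategorical(rep("only", 4)), "single category")
})

test_that("indicator and Helmert codings span the same model fit", {
  set.seed(42)
  n <- 30
  g <- sample(c("a", "b", "c"), n, replace = TRUE)
  y1 <- rnorm(n, ifelse(g == "a", 0, ifelse(g == "b", 1, 2)))
  y2 <- rnorm(n, ifelse(g == "a", 2, 0))
  d <- wide_data(y1, y2, data.frame(G = g))
  f_ind <- fit_difference_model(d, mod_spec("additive", scheme = "indicator"))
  f_hel <- fit_difference_model(d, mod_spec("additive", scheme = "helmert"))
  expect_equal(f_ind$r2, f_hel$r2, tolerance = 1e-12)
  expect_equal(f_ind$F$statistic, f_hel$F$statistic, tolerance = 1e-12)
})

test_that("centering changes nothing substantive about the additive fit", {
  set.seed(99)
  d <- rand_fixture(n = 35, m = 2)
  f_raw <- fit_difference_model(d, mod_spec("additive", center = FALSE))
  f_cen <- fit_difference_model(d, mod_spec("additive", center = TRUE))
  # same response, same explained variance, same non-intercept coefficients
  expect_equal(f_cen$r2, f_raw$r2, tolerance = 1e-12)
  expect_equal(unname(f_cen$b[-1]), unname(f_raw$b[-1]), tolerance = 1e-10)

  # JN roots back on the original scale are unchanged by centering
  d1 <- rand_fixture(n = 35, m = 1, seed = 123)
  fr <- fit_difference_model(d1, mod_spec(center = FALSE))
  fc <- fit_difference_model(d1, mod_spec(center = TRUE))
  jr <- jn_points(fr, fr$data$w$W1)
  jc <- jn_points(fc, fc$data$w$W1)
  if (length(jr$roots)) {
    expect_equal(jc$roots + fc$data$w_means["W1"], jr$roots,
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})
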