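#' Moderator sampling specifications
#'
#' Helpers describing how each between-participant moderator is drawn in
#' [generate_two_instance()]: standard choices are a normal moderator (e.g. a
#' standardized biomarker score) or a Bernoulli 0/1 moderator (e.g. random
#' assignment to one of two therapies).
#'
#' @param mean,sd Normal parameters.
#' @param p Success probability for a 0/1 moderator.
#' @param min,max Uniform bounds.
#' @return A distribution spec used by [generate_two_instance()].
#' @name moderator_dists
NULL

#' @rdname moderator_dists
#' @export
mod_normal <- function(mean = 0, sd = 1) {
  stopifnot(is.finite(mean), is.finite(sd), sd >= 0)
  structure(list(dist = "normal", mean = mean, sd = sd), class = "mod_dist")
}

#' @rdname moderator_dists
#' @export
mod_bernoulli <- function(p = 0.5) {
  stopifnot(p >= 0, p <= 1)
  structure(list(dist = "bernoulli", p = p), class = "mod_dist")
}

#' @rdname moderator_dists
#' @export
mod_uniform <- function(min = 0, max = 1) {
  stopifnot(is.finite(min), is.finite(max), max > min)
  structure(list(dist = "uniform", min = min, max = max), class = "mod_dist")
}

draw_moderator <- function(spec, n) {
  if (!inherits(spec, "mod_dist"))
    stop("moderator distribution must be built with mod_normal(), ",
         "mod_bernoulli() or mod_uniform()", call. = FALSE)
  switch(spec$dist,
         normal = stats::rnorm(n, spec$mean, spec$sd),
         bernoulli = stats::rbinom(n, 1, spec$p),
         uniform = stats::runif(n, spec$min, spec$max))
}

#' Generate a two-instance repeated measures dataset
#'
#' Simulates the generating model behind the difference-score analysis:
#' each participant's outcome in condition j = 1, 2 is
#' \deqn{Y_{ij} = b_{0j} + \sum_k b_{kj} W_{ki} + \epsilon_{ij}}
#' with moderators drawn per \code{w_dist} and the within-person error pair
#' (\eqn{\epsilon_{i1}, \epsilon_{i2}}) bivariate normal with standard
#' deviations \code{sigma1}, \code{sigma2} and correlation \code{rho}
#' (independent across participants). The difference of the two conditions
#' therefore has residual variance
#' \eqn{\sigma_1^2 + \sigma_2^2 - 2\rho\sigma_1\sigma_2}.
#'
#' Defaults emulate a behavioural chronic-pain trial: 40 participants, one
#' standardized continuous moderator (baseline inflammation), per-condition
#' slopes 0.0293 and 0.43 (so the condition effect declines by about 0.4
#' outcome units per moderator unit), error SDs 1.2 and within-person error
#' correlation 0.5.
#'
#' @param n Number of participants.
#' @param b_cond1,b_cond2 Per-condition coefficient vectors (intercept first),
#'   equal length 1 + m.
#' @param sigma1,sigma2 Error standard deviations in each condition (>= 0).
#' @param rho Within-person error correlation in [-1, 1].
#' @param w_dist List of m moderator distribution specs (see
#'   [moderator_dists]).
#' @param seed Optional integer seed; the same seed reproduces the same
#'   dataset.
#' @return A [wide_data()] object with outcome columns \code{y1}, \code{y2}
#'   and moderators \code{W1..Wm}; the generating parameters are attached as
#'   attribute \code{"gen_params"}.
#' @export
generate_two_instance <- function(n = 40,
                                  b_cond1 = c(3.5, 0.0293),
                                  b_cond2 = c(3.3, 0.43),
                                  sigma1 = 1.2, sigma2 = 1.2, rho = 0.5,
                                  w_dist = list(mod_normal()),
                                  seed = NULL) {
  stopifnot(n >= 3, sigma1 >= 0, sigma2 >= 0, rho >= -1, rho <= 1,
            length(b_cond1) == length(b_cond2),
            length(b_cond1) == length(w_dist) + 1L)
  if (!is.null(seed)) set.seed(seed)
  m <- length(w_dist)
  W <- vapply(w_dist, draw_moderator, numeric(n), n = n)
  W <- matrix(W, nrow = n)
  colnames(W) <- paste0("W", seq_len(m))
  S <- matrix(c(sigma1^2, rho * sigma1 * sigma2,
                rho * sigma1 * sigma2, sigma2^2), 2, 2)
  eps <- MASS::mvrnorm(n, mu = c(0, 0), Sigma = S)
  Xd <- cbind(1, W)
  y1 <- drop(Xd %*% b_cond1) + eps[, 1]
  y2 <- drop(Xd %*% b_cond2) + eps[, 2]
  d <- wide_data(y1, y2, as.data.frame(W), y_names = c("y1", "y2"))
  attr(d, "gen_params") <- list(n = n, b_cond1 = b_cond1, b_cond2 = b_cond2,
                                sigma1 = sigma1, sigma2 = sigma2, rho = rho,
                                w_dist = w_dist, seed = seed)
  d
}

#' Write a generated dataset as a CSV readable by read_wide_csv
#'
#' @param d A [wide_data()] object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_wide_csv <- function(d, path) {
  stopifnot(inherits(d, "wide_data"))
  df <- data.frame(d$y1, d$y2, d$w)
  names(df) <- c(d$y_names, d$w_names)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Operating characteristics of the interaction test by simulation
#'
#' Repeatedly generates two-instance data and fits the difference-score
#' model, summarising the rejection rate of the highest-order interaction
#' test (for one moderator, the condition-by-moderator interaction), the mean
#' and SD of every coefficient estimate, and optionally the coverage of the
#' confidence interval for the conditional condition effect at given
#' moderator values. Under b_cond1 = b_cond2 the rejection rate estimates the
#' type-I error; under unequal slopes it estimates power.
#'
#' The response is the condition-2 minus condition-1 difference, so the
#' estimand for each coefficient is \code{b_cond2 - b_cond1}.
#'
#' @inheritParams generate_two_instance
#' @param reps Number of simulated datasets (>= 1).
#' @param alpha Test level.
#' @param probe_at Optional numeric vector (or list of vectors) of moderator
#'   values at which CI coverage of the conditional effect is tracked.
#' @param seed Integer seed; replicate r uses the deterministic stream
#'   \code{seed + r}, so any replicate can be regenerated on its own.
#' @return List of class \code{"sim_summary"}: \code{rejection_rate},
#'   \code{coef_mean}, \code{coef_sd}, \code{coverage} (or \code{NULL}),
#'   \code{reps}, \code{alpha}.
#' @export
simulate_test <- function(n = 40, b_cond1 = c(3.5, 0.0293),
                          b_cond2 = c(3.3, 0.43),
                          sigma1 = 1.2, sigma2 = 1.2, rho = 0.5,
                          w_dist = list(mod_normal()),
                          reps = 1000, alpha = 0.05,
                          probe_at = NULL, seed = 1L) {
  stopifnot(reps >= 1)
  # additive design matches the main-effects generating model for any m
  spec <- mod_spec(model = "additive", center = FALSE, alpha = alpha)
  p <- length(b_cond1)
  true_b <- b_cond2 - b_cond1
  est <- matrix(NA_real_, reps, p)
  reject <- logical(reps)
  cover <- if (!is.null(probe_at)) {
    if (!is.list(probe_at)) probe_at <- lapply(probe_at, identity)
    matrix(NA, reps, length(probe_at))
  }
  for (r in seq_len(reps)) {
    d <- generate_two_instance(n, b_cond1, b_cond2, sigma1, sigma2, rho,
                               w_dist, seed = seed + r)
    # condition-2 minus condition-1 difference: estimand is b_cond2 - b_cond1
    d2 <- wide_data(d$y2, d$y1, d$w, y_names = c("y2", "y1"),
                    w_names = d$w_names)
    fit <- fit_difference_model(d2, spec)
    est[r, ] <- fit$b
    reject[r] <- fit$table$p[nrow(fit$table)] < alpha
    if (!is.null(probe_at)) {
      for (k in seq_along(probe_at)) {
        at <- as.numeric(probe_at[[k]])
        theta_true <- sum(build_contrast(at, fit) * true_b)
        ce <- conditional_effect(fit, build_contrast(at, fit), alpha = alpha)
        cover[r, k] <- ce$ci_low <= theta_true && theta_true <= ce$ci_high
      }
    }
  }
  structure(list(rejection_rate = mean(reject),
                 coef_mean = colMeans(est), coef_sd = apply(est, 2, stats::sd),
                 coverage = if (!is.null(probe_at)) colMeans(cover),
                 reps = reps, alpha = alpha, true_b = true_b),
            class = "sim_summary")
}

#' @export
print.sim_summary <- function(x, digits = 4, ...) {
  cat("Simulation summary (", x$reps, " replicates, alpha = ",
      format(x$alpha), ")\n", sep = "")
  cat(sprintf("  interaction rejection rate: %.*f\n", digits,
              x$rejection_rate))
  cat("  coefficient means:", paste(formatC(x$coef_mean, digits = digits,
                                            format = "f"), collapse = " "),
      "\n")
  if (!is.null(x$coverage))
    cat("  CI coverage:", paste(formatC(x$coverage, digits = digits,
                                        format = "f"), collapse = " "), "\n")
  invisible(x)
}
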