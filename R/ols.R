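#' Build the moderator design matrix
#'
#' Constructs the design for the difference-score regression (and the matching
#' per-condition regressions): an intercept plus one column per moderator
#' term. Additive models use the m moderator columns; multiplicative models
#' use all products over nonempty subsets of the moderators (2^m - 1 columns),
#' ordered by subset size and then input order. Products are formed from the
#' columns as stored, so centering (when on) happens before products are
#' taken.
#'
#' @param d A [wide_data()] object with all-numeric moderators (categorical
#'   moderators must be coded first; see [encode_multicategorical()]).
#' @param spec A [mod_spec()] object (only \code{$model} is used).
#' @return A numeric matrix with an attribute \code{"term_sets"} (a list, one
#'   integer vector of moderator indices per column; \code{integer(0)} for the
#'   intercept) and column names \code{"constant"} and the term labels.
#' @export
build_design <- function(d, spec) {
  stopifnot(inherits(d, "wide_data"))
  if (any(d$w_cat))
    stop("categorical moderators must be coded before building the design",
         call. = FALSE)
  m <- length(d$w)
  sets <- list(integer(0))
  if (spec$model == "additive" || m == 1L) {
    sets <- c(sets, as.list(seq_len(m)))
  } else {
    for (size in seq_len(m))
      sets <- c(sets, utils::combn(m, size, simplify = FALSE))
  }
  X <- vapply(sets, function(s) {
    if (!length(s)) rep(1, d$n) else Reduce(`*`, d$w[s])
  }, numeric(d$n))
  labels <- vapply(sets, function(s) {
    if (!length(s)) "constant" else paste(d$w_names[s], collapse = "*")
  }, character(1))
  colnames(X) <- labels
  check_full_rank(X)
  attr(X, "term_sets") <- sets
  X
}

# Deterministic singularity check: exact rank via QR, plus a condition-number
# threshold of 1e12 on the column-scaled design for near-singularity.
check_full_rank <- function(X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop("singular design: column(s) ", paste(bad, collapse = ", "),
         " are collinear with the others", call. = FALSE)
  }
  scale <- apply(abs(X), 2, max)
  Xs <- sweep(X, 2, scale, "/")
  if (kappa(Xs, exact = TRUE) > 1e12)
    stop("design is numerically singular (condition number > 1e12)",
         call. = FALSE)
  invisible(X)
}

#' Ordinary least squares with coefficient covariance matrix
#'
#' Fits \code{y ~ X} by QR decomposition and returns everything the probing
#' machinery needs: coefficients, their estimated covariance matrix
#' \eqn{\hat\sigma^2 (X'X)^{-1}} with the unbiased residual-variance
#' denominator \eqn{n - q - 1}, the model R-squared and overall F test, and a
#' per-coefficient inference table (t, two-sided p, confidence interval).
#'
#' @param y Numeric response vector.
#' @param X Design matrix including an intercept column (see
#'   [build_design()]).
#' @param alpha Level for the coefficient confidence intervals.
#' @return An object of class \code{"rm_fit"}: list with \code{b},
#'   \code{Sigma}, \code{df}, \code{sigma2}, \code{r2}, \code{F} (statistic,
#'   numerator/denominator df, p; \code{NA} when undefined), \code{n},
#'   \code{q}, \code{labels}, \code{table} (coefficient data frame),
#'   \code{term_sets}, \code{alpha}.
#' @export
ols_fit <- function(y, X, alpha = 0.05) {
  n <- length(y)
  if (n != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  p <- ncol(X)
  q <- p - 1L
  if (n - q - 1L < 1L)
    stop("too few observations: n - q - 1 must be >= 1", call. = FALSE)
  check_full_rank(X)
  qx <- qr(X)
  b <- drop(qr.coef(qx, y))
  res <- drop(qr.resid(qx, y))
  sse <- sum(res^2)
  df <- n - q - 1L
  sigma2 <- sse / df
  # (X'X)^{-1} from the R factor, undoing any pivot
  Rinv <- chol2inv(qr.R(qx))
  xtx_inv <- matrix(0, p, p)
  piv <- qx$pivot
  xtx_inv[piv, piv] <- Rinv
  Sigma <- sigma2 * xtx_inv
  dimnames(Sigma) <- list(colnames(X), colnames(X))
  sst <- sum((y - mean(y))^2)
  if (sst > 0) {
    r2 <- 1 - sse / sst
    Fstat <- if (q >= 1L) ((sst - sse) / q) / sigma2 else NA_real_
  } else {
    r2 <- NA_real_  # constant response: R^2 undefined
    Fstat <- NA_real_
  }
  Fp <- if (is.finite(Fstat)) stats::pf(Fstat, q, df, lower.tail = FALSE)
        else NA_real_
  se <- sqrt(pmax(diag(Sigma), 0))
  tval <- ifelse(se > 0, b / se, NA_real_)
  pval <- 2 * stats::pt(-abs(tval), df)
  tcrit <- critical_t(alpha, df)
  tab <- data.frame(term = colnames(X), estimate = b, se = se, t = tval,
                    p = pval, ci_low = b - tcrit * se, ci_high = b + tcrit * se,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(b = stats::setNames(b, colnames(X)), Sigma = Sigma, df = df,
                 sigma2 = sigma2, r2 = r2,
                 F = list(statistic = Fstat, df1 = q, df2 = df, p = Fp),
                 n = n, q = q, labels = colnames(X), table = tab,
                 term_sets = attr(X, "term_sets"), alpha = alpha),
            class = "rm_fit")
}

#' Assemble a fit summary from externally given coefficients
#'
#' Builds an \code{"rm_fit"} object directly from a coefficient vector, its
#' covariance matrix and the residual degrees of freedom, e.g. from a
#' published regression table. Conditional effects computed from such a
#' summary reproduce desk calculations based on printed output.
#'
#' @param b Coefficient vector (intercept first).
#' @param Sigma Coefficient covariance matrix (for a printed table with
#'   standard errors \code{se} and no reported covariances,
#'   \code{diag(se^2)}).
#' @param df Residual degrees of freedom, n - q - 1.
#' @param labels Optional term labels.
#' @param term_sets Optional term structure (as produced by
#'   [build_design()]); defaults to intercept + one main effect per
#'   coefficient.
#' @param alpha Level for intervals.
#' @return An object of class \code{"rm_fit"}.
#' @export
fit_summary <- function(b, Sigma, df, labels = NULL, term_sets = NULL,
                        alpha = 0.05) {
  p <- length(b)
  Sigma <- as.matrix(Sigma)
  stopifnot(nrow(Sigma) == p, ncol(Sigma) == p, df >= 1)
  if (is.null(labels))
    labels <- c("constant", paste0("W", seq_len(p - 1L)))
  if (is.null(term_sets))
    term_sets <- c(list(integer(0)), as.list(seq_len(p - 1L)))
  se <- sqrt(pmax(diag(Sigma), 0))
  tval <- ifelse(se > 0, b / se, NA_real_)
  pval <- 2 * stats::pt(-abs(tval), df)
  tcrit <- critical_t(alpha, df)
  tab <- data.frame(term = labels, estimate = b, se = se, t = tval, p = pval,
                    ci_low = b - tcrit * se, ci_high = b + tcrit * se,
                    row.names = NULL, stringsAsFactors = FALSE)
  dimnames(Sigma) <- list(labels, labels)
  structure(list(b = stats::setNames(as.numeric(b), labels), Sigma = Sigma,
                 df = as.integer(df), sigma2 = NA_real_, r2 = NA_real_,
                 F = list(statistic = NA_real_, df1 = p - 1L,
                          df2 = as.integer(df), p = NA_real_),
                 n = as.integer(df + p), q = p - 1L, labels = labels,
                 table = tab, term_sets = term_sets, alpha = alpha),
            class = "rm_fit")
}

#' Fit the difference-score moderation model
#'
#' The interaction test for a two-instance design: the within-person
#' difference (first-listed minus second-listed outcome) is regressed on the
#' moderator design. Each non-intercept coefficient estimates how much the
#' corresponding moderator term shifts the condition effect, i.e. the
#' condition-by-term interaction; the intercept estimates the condition effect
#' when every moderator term is zero.
#'
#' @param d A [wide_data()] object.
#' @param spec A [mod_spec()] object.
#' @return An \code{"rm_fit"} (see [ols_fit()]) with additional fields
#'   \code{data} (the prepared, centered dataset) and \code{X} (the design).
#' @export
fit_difference_model <- function(d, spec = mod_spec()) {
  d <- expand_categorical(d, spec$scheme)
  d <- center_moderators(d, spec$center)
  X <- build_design(d, spec)
  fit <- ols_fit(make_difference(d), X, alpha = spec$alpha)
  fit$data <- d
  fit$X <- X
  fit
}

#' Fit the per-condition regressions
#'
#' Regresses each instance's outcome on the same moderator design. The
#' non-intercept coefficients are the simple slopes of each moderator within
#' that condition; their difference across conditions equals the
#' corresponding difference-model coefficient exactly.
#'
#' @inheritParams fit_difference_model
#' @return List of class \code{"condition_fits"} with elements \code{fit1}
#'   and \code{fit2} (class \code{"rm_fit"}) and \code{y_names}.
#' @export
fit_per_condition <- function(d, spec = mod_spec()) {
  d <- expand_categorical(d, spec$scheme)
  d <- center_moderators(d, spec$center)
  X <- build_design(d, spec)
  structure(list(fit1 = ols_fit(d$y1, X, alpha = spec$alpha),
                 fit2 = ols_fit(d$y2, X, alpha = spec$alpha),
                 y_names = d$y_names),
            class = "condition_fits")
}

#' @export
print.rm_fit <- function(x, digits = 4, ...) {
  cat("Difference-score regression fit\n")
  cat(sprintf("  n = %d, q = %d, df = %d\n", x$n, x$q, x$df))
  if (is.finite(x$r2))
    cat(sprintf("  R^2 = %.*f, F(%d, %d) = %.*f, p = %.*f\n", digits, x$r2,
                x$F$df1, x$F$df2, digits, x$F$statistic, digits, x$F$p))
  print(format_num_df(x$table, digits))
  invisible(x)
}
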