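#' Two-sided critical t value
#'
#' Upper critical value of Student's t for a two-sided test at level
#' \code{alpha}: the 1 - alpha/2 quantile.
#'
#' @param alpha Significance level in (0, 1).
#' @param df Degrees of freedom (>= 1).
#' @return A single numeric value.
#' @export
critical_t <- function(alpha, df) {
  stopifnot(alpha > 0, alpha < 1, df >= 1)
  stats::qt(1 - alpha / 2, df)
}

#' Contrast vector for the condition effect at fixed moderator values
#'
#' The conditional effect of condition at a point (W1, ..., Wm) is the linear
#' combination l'b of the difference-model coefficients, where each entry of
#' l is the corresponding design term evaluated at that point: 1 for the
#' intercept, the moderator value for a main-effect term, and the product of
#' the involved moderator values for a product term.
#'
#' @param at Numeric vector of moderator values, one per moderator, on the
#'   analysis (centered) scale.
#' @param term_sets Term structure of the design: either a design matrix from
#'   [build_design()], an \code{"rm_fit"}, or the \code{"term_sets"} list
#'   itself.
#' @return Numeric contrast vector l, one weight per coefficient.
#' @export
build_contrast <- function(at, term_sets) {
  sets <- extract_term_sets(term_sets)
  m <- max(c(0L, unlist(sets)))
  if (length(at) != m)
    stop("'at' must supply one value per moderator (", m, ")", call. = FALSE)
  vapply(sets, function(s) if (!length(s)) 1 else prod(at[s]), numeric(1))
}

extract_term_sets <- function(x) {
  sets <- if (inherits(x, "rm_fit")) x$term_sets
          else if (is.matrix(x)) attr(x, "term_sets")
          else x
  if (is.null(sets)) stop("no term structure available", call. = FALSE)
  sets
}

#' Conditional effect l'b with contrast-vector standard error
#'
#' Point estimate, standard error, t ratio, two-sided p value and confidence
#' interval for a linear combination l'b of regression coefficients. The
#' variance is l' Sigma l, with Sigma the estimated coefficient covariance
#' matrix, and the t ratio is referred to a t distribution with n - q - 1
#' degrees of freedom.
#'
#' @param fit An \code{"rm_fit"} object.
#' @param l Contrast vector (see [build_contrast()]).
#' @param alpha Level for the confidence interval; defaults to the fit's.
#' @param at Optional moderator values to record alongside the estimate.
#' @return A one-row data frame of class \code{"conditional_effect"} with
#'   columns for the probed values, \code{estimate}, \code{se}, \code{t},
#'   \code{p}, \code{ci_low}, \code{ci_high}.
#' @export
conditional_effect <- function(fit, l, alpha = fit$alpha, at = NULL) {
  stopifnot(inherits(fit, "rm_fit"))
  if (length(l) != length(fit$b))
    stop("contrast length must match the number of coefficients",
         call. = FALSE)
  if (!all(is.finite(fit$Sigma)))
    stop("coefficient covariance matrix has non-finite entries",
         call. = FALSE)
  est <- sum(l * fit$b)
  v <- drop(t(l) %*% fit$Sigma %*% l)
  se <- sqrt(max(v, 0))
  tval <- if (se > 0) est / se else NA_real_
  pval <- 2 * stats::pt(-abs(tval), fit$df)
  tcrit <- critical_t(alpha, fit$df)
  out <- data.frame(estimate = est, se = se, t = tval, p = pval,
                    ci_low = est - tcrit * se, ci_high = est + tcrit * se)
  if (!is.null(at)) {
    atdf <- as.data.frame(as.list(at))
    names(atdf) <- if (!is.null(names(at))) names(at)
                   else paste0("W", seq_along(at))
    out <- cbind(atdf, out)
  }
  class(out) <- c("conditional_effect", "data.frame")
  out
}

#' Default probe values for a continuous moderator
#'
#' Values of the moderator at which the condition effect is probed:
#' the mean and the mean plus/minus one standard deviation (default), the
#' 16th/50th/84th percentiles (guaranteed to lie inside the observed range;
#' computed by linear interpolation between order statistics, R quantile
#' type 7), or a custom list passed through unchanged.
#'
#' @param w Numeric moderator column.
#' @param mode \code{"meansd"}, \code{"percentile"} or \code{"custom"}.
#' @param values Probe values for \code{mode = "custom"}.
#' @return Sorted numeric vector of probe values.
#' @export
default_probe_points <- function(w, mode = c("meansd", "percentile", "custom"),
                                 values = NULL) {
  mode <- match.arg(mode)
  if (mode == "custom") {
    stopifnot(is.numeric(values), all(is.finite(values)))
    return(as.numeric(values))
  }
  if (!is_continuous_column(w))
    stop("default probe points require a continuous moderator; ",
         "probe dichotomous moderators at their observed values",
         call. = FALSE)
  switch(mode,
         meansd = mean(w) + c(-1, 0, 1) * stats::sd(w),
         percentile = unname(stats::quantile(w, c(.16, .50, .84), type = 7)))
}

#' Pick-a-point table of conditional condition effects
#'
#' Probes the condition effect at every combination of the supplied
#' per-moderator values (Cartesian product, last moderator varying fastest),
#' with one [conditional_effect()] row per combination.
#'
#' @param fit A difference-model \code{"rm_fit"}.
#' @param points List with one numeric vector of probe values per moderator,
#'   on the analysis (centered) scale.
#' @param alpha Level for intervals; defaults to the fit's.
#' @return Data frame with the probed values and the effect columns.
#' @export
pick_a_point_table <- function(fit, points, alpha = fit$alpha) {
  stopifnot(inherits(fit, "rm_fit"), is.list(points))
  m <- max(c(0L, unlist(fit$term_sets)))
  if (length(points) != m)
    stop("'points' must have one value list per moderator (", m, ")",
         call. = FALSE)
  grid <- rev(expand.grid(rev(points)))  # last moderator varies fastest
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    at <- as.numeric(grid[i, ])
    conditional_effect(fit, build_contrast(at, fit), alpha = alpha, at = at)
  })
  out <- do.call(rbind, rows)
  if (!is.null(names(points)) && all(nzchar(names(points))))
    names(out)[seq_len(m)] <- names(points)
  rownames(out) <- NULL
  out
}
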