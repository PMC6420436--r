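#' Johnson-Neyman boundaries of significance
#'
#' For a single continuous moderator W, finds the values of W at which the
#' conditional effect of condition, theta(W) = b0 + b1 W, is exactly
#' significant at level alpha: the solutions of
#' \deqn{|b0 + b1 W| / \sqrt{var(b0) + W^2 var(b1) + 2 W cov(b0, b1)} = t^*}
#' Squaring and rearranging gives the quadratic a W^2 + b W + c = 0 with
#' \deqn{a = b1^2 - t^{*2} var(b1)}
#' \deqn{b = 2 b1 b0 - 2 t^{*2} cov(b0, b1)}
#' \deqn{c = b0^2 - t^{*2} var(b0)}
#' solved in closed form. Solutions can be complex or lie outside the observed
#' moderator range; those are retained with flags but only in-range real roots
#' are reported as boundaries, and no significance claims are made beyond the
#' data. A region table of conditional effects over the observed range (an
#' evenly spaced grid with the in-range roots spliced in) summarises where the
#' condition effect is and is not significant.
#'
#' @param fit A difference-model \code{"rm_fit"} from a single-moderator
#'   model (q = 1).
#' @param w The observed moderator values on the same (analysis) scale as the
#'   fit; used for range filtering and the percentage of data above each
#'   boundary.
#' @param alpha Significance level; defaults to the fit's.
#' @param grid_n Number of evenly spaced grid points in the region table.
#' @return An object of class \code{"jn_result"}: list with \code{roots}
#'   (in-range, ascending), \code{pct_above} (percent of observed W strictly
#'   above each root), \code{all_roots} (data frame of both raw solutions
#'   with \code{real} and \code{in_range} flags), \code{region_table},
#'   \code{t_crit}, \code{alpha}, \code{range}.
#' @export
jn_points <- function(fit, w, alpha = fit$alpha, grid_n = 21L) {
  stopifnot(inherits(fit, "rm_fit"))
  if (fit$q != 1L)
    stop("the Johnson-Neyman procedure is implemented for a single moderator",
         call. = FALSE)
  if (length(unique(w)) < 3L)
    stop("the Johnson-Neyman procedure is limited to continuous moderators ",
         "(moderator has fewer than 3 distinct values)", call. = FALSE)
  tcrit <- critical_t(alpha, fit$df)
  b0 <- fit$b[1]; b1 <- fit$b[2]
  v0 <- fit$Sigma[1, 1]; v1 <- fit$Sigma[2, 2]; c01 <- fit$Sigma[1, 2]
  qa <- b1^2 - tcrit^2 * v1
  qb <- 2 * b1 * b0 - 2 * tcrit^2 * c01
  qc <- b0^2 - tcrit^2 * v0
  scale <- max(abs(c(b1^2, tcrit^2 * v1, 1)))
  rng <- range(w)

  if (abs(qa) < 1e-12 * scale) {
    raw <- if (abs(qb) > 0) -qc / qb else numeric(0)  # degenerate: linear
    real <- rep(TRUE, length(raw))
  } else {
    disc <- qb^2 - 4 * qa * qc
    if (disc < 0) {
      raw <- rep(NA_real_, 2)
      real <- c(FALSE, FALSE)
    } else {
      raw <- sort((-qb + c(-1, 1) * sqrt(disc)) / (2 * qa))
      real <- c(TRUE, TRUE)
    }
  }
  in_range <- real & raw >= rng[1] & raw <= rng[2]
  in_range[is.na(in_range)] <- FALSE
  all_roots <- data.frame(root = unname(raw), real = real,
                          in_range = in_range)
  roots <- sort(raw[in_range])
  pct_above <- vapply(roots, function(r) 100 * mean(w > r), numeric(1))

  grid <- sort(unique(c(seq(rng[1], rng[2], length.out = grid_n), roots)))
  region <- do.call(rbind, lapply(grid, function(v)
    conditional_effect(fit, c(1, v), alpha = alpha, at = c(W = v))))
  region$significant <- abs(region$t) > tcrit - 1e-12  # roots count as boundary
  rownames(region) <- NULL

  structure(list(roots = unname(roots), pct_above = unname(pct_above),
                 all_roots = all_roots, region_table = region,
                 t_crit = tcrit, alpha = alpha, range = rng),
            class = "jn_result")
}

#' Export the Johnson-Neyman region table as a tidy CSV
#'
#' Writes one row per region-table grid point with the moderator value, the
#' conditional condition effect, its confidence bounds and the significance
#' flag, suitable for plotting the conditional effect with its confidence
#' band and marking where the band crosses zero.
#'
#' @param jn A \code{"jn_result"} object.
#' @param path Output file path.
#' @return The exported data frame, invisibly.
#' @export
export_jn_plot <- function(jn, path) {
  stopifnot(inherits(jn, "jn_result"))
  out <- jn$region_table[, c("W", "estimate", "ci_low", "ci_high",
                             "significant")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' @export
print.jn_result <- function(x, digits = 4, ...) {
  cat("Johnson-Neyman boundaries of significance (alpha =",
      format(x$alpha), ")\n")
  cat(sprintf("  critical t = %.*f; observed moderator range [%.*f, %.*f]\n",
              digits, x$t_crit, digits, x$range[1], digits, x$range[2]))
  if (!length(x$roots)) {
    cat("  no boundaries inside the observed range\n")
  } else {
    for (i in seq_along(x$roots))
      cat(sprintf("  W = %.*f  (%.2f%% of the data above)\n", digits,
                  x$roots[i], x$pct_above[i]))
  }
  invisible(x)
}
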