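#' Moderation analysis for a two-instance repeated measures design
#'
#' One-stop analysis: reads or accepts wide-form data, fits the
#' difference-score regression that carries the condition-by-moderator
#' interaction test, probes the conditional effect of condition at moderator
#' values (pick-a-point), reports the per-condition moderator effects, and
#' (optionally, single continuous moderator) runs the Johnson-Neyman
#' procedure. Printing the returned object renders the full plain-text
#' report.
#'
#' @param data A data frame in wide form (one row per participant), a
#'   [wide_data()] object, or a path to a CSV file.
#' @param y Character vector of length 2: outcome columns for the first and
#'   second instance; the analysed difference is first minus second. Ignored
#'   when \code{data} is already a \code{wide_data}.
#' @param w Character vector of moderator columns. Ignored for
#'   \code{wide_data} input.
#' @param model \code{"additive"} (numeric code 2 on the command line) or
#'   \code{"multiplicative"} (code 3); with one moderator the two coincide.
#' @param center Mean-center continuous moderators (default \code{TRUE}).
#' @param alpha Significance level (default 0.05).
#' @param jn Request the Johnson-Neyman procedure.
#' @param probe \code{"meansd"} (default) or \code{"percentile"} for the
#'   automatic probe values of continuous moderators.
#' @param wmodval Optional list with one numeric vector of additional probe
#'   values per moderator, on the original (uncentered) scale.
#' @param scheme Coding for categorical moderators: \code{"indicator"} or
#'   \code{"helmert"}.
#' @return An object of class \code{"rmmod"}; see Details.
#'
#' @details The returned list contains \code{data} (prepared dataset:
#'   categorical moderators coded, continuous ones centered), \code{spec},
#'   \code{fit} (difference-score \code{"rm_fit"}), \code{cond_fits}
#'   (per-condition fits), \code{probe_points} (per-moderator values on the
#'   analysis scale), \code{pick} (pick-a-point table), \code{jn}
#'   (\code{"jn_result"}, or a character message when the procedure was
#'   refused or not requested).
#' @export
rmmod <- function(data, y, w, model = c("additive", "multiplicative"),
                  center = TRUE, alpha = 0.05, jn = FALSE,
                  probe = c("meansd", "percentile"), wmodval = NULL,
                  scheme = c("indicator", "helmert")) {
  probe <- match.arg(probe)
  spec <- mod_spec(model = match.arg(model), center = center, alpha = alpha,
                   jn = jn, scheme = match.arg(scheme))
  d <- if (inherits(data, "wide_data")) data
       else if (is.character(data)) read_wide_csv(data, y, w)
       else {
         df <- as.data.frame(data)
         missing_cols <- setdiff(c(y, w), names(df))
         if (length(missing_cols))
           stop("column(s) not found: ",
                paste(missing_cols, collapse = ", "), call. = FALSE)
         keep <- stats::complete.cases(df[, c(y, w), drop = FALSE])
         wide_data(df[keep, y[1]], df[keep, y[2]],
                   df[keep, w, drop = FALSE], y_names = y, w_names = w,
                   n_dropped = sum(!keep))
       }

  fit <- fit_difference_model(d, spec)
  prepared <- fit$data
  cond_fits <- fit_per_condition(d, spec)

  if (!is.null(wmodval)) {
    if (!is.list(wmodval)) wmodval <- list(wmodval)
    if (length(wmodval) != length(prepared$w))
      stop("wmodval must supply one value list per moderator (after any ",
           "categorical coding: ", length(prepared$w), ")", call. = FALSE)
  }
  probe_points <- lapply(seq_along(prepared$w), function(j) {
    wj <- prepared$w[[j]]
    auto <- if (is_continuous_column(wj)) default_probe_points(wj, probe)
            else sort(unique(wj))
    extra <- if (!is.null(wmodval)) {
      v <- as.numeric(wmodval[[j]])
      # user values arrive on the original scale
      if (prepared$centered[j]) v - prepared$w_means[j] else v
    } else numeric(0)
    sort(unique(c(auto, extra)))
  })
  names(probe_points) <- prepared$w_names
  pick <- pick_a_point_table(fit, probe_points, alpha = alpha)

  jn_out <- if (!spec$jn) {
    "not requested"
  } else if (length(prepared$w) != 1L) {
    "refused: the Johnson-Neyman procedure is reported only for a single moderator"
  } else if (!is_continuous_column(prepared$w[[1]])) {
    "refused: the Johnson-Neyman procedure is limited to continuous moderators"
  } else {
    jn_points(fit, prepared$w[[1]], alpha = alpha)
  }

  structure(list(call = match.call(), data = prepared, spec = spec,
                 fit = fit, cond_fits = cond_fits,
                 probe_points = probe_points, pick = pick, jn = jn_out),
            class = "rmmod")
}

#' @export
print.rmmod <- function(x, digits = 4, ...) {
  cat(render_report(x, digits = digits), sep = "\n")
  invisible(x)
}
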