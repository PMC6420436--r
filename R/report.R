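# Fixed-precision rendering of a data frame of results. Numbers are printed
# with a fixed number of decimals so identical inputs give byte-identical
# reports.
format_num_df <- function(df, digits = 4) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = digits, format = "f")
  }
  out
}

render_table <- function(df, digits = 4, indent = "  ") {
  f <- format_num_df(df, digits)
  f[] <- lapply(f, as.character)
  widths <- pmax(nchar(names(f)), vapply(f, function(col)
    max(c(0L, nchar(col))), integer(1)))
  pad <- function(cells) paste(mapply(formatC, cells, width = widths,
                                      MoreArgs = list(flag = "-")),
                               collapse = "  ")
  c(paste0(indent, pad(names(f))),
    vapply(seq_len(nrow(f)), function(i)
      paste0(indent, pad(unlist(f[i, ], use.names = FALSE))), character(1)))
}

#' Render the plain-text analysis report
#'
#' Produces the full report for a fitted [rmmod()] analysis: model
#' information (variables, roles, subtraction order, sample size, centering),
#' the overall difference-score model, the coefficient table, the
#' pick-a-point table of conditional condition effects, the per-condition
#' moderator effects, and the Johnson-Neyman section. All numbers come from
#' the stored fit objects; nothing is recomputed here. Identical inputs give
#' byte-identical output.
#'
#' @param x An \code{"rmmod"} object.
#' @param digits Fixed number of decimals (default 4).
#' @return Character vector of report lines.
#' @export
render_report <- function(x, digits = 4) {
  stopifnot(inherits(x, "rmmod"))
  d <- x$data; fit <- x$fit
  rule <- strrep("*", 64)
  lines <- c(rule,
             "Moderation analysis for two-instance repeated measures designs",
             rule, "")

  kinds <- ifelse(vapply(d$w, is_continuous_column, logical(1)),
                  ifelse(d$centered, "continuous, mean-centered",
                         "continuous"),
                  "dichotomous/coded")
  lines <- c(lines, "Model information",
    paste0("  Outcomes   : ", d$y_names[1], " (instance 1), ", d$y_names[2],
           " (instance 2)"),
    paste0("  Difference : ", d$y_names[1], " - ", d$y_names[2]),
    paste0("  Moderators : ",
           paste(sprintf("%s (%s)", d$w_names, kinds), collapse = "; ")),
    paste0("  Model type : ", x$spec$model,
           if (length(d$w) == 1L) " (single moderator)" else ""),
    paste0("  Sample     : n = ", d$n, "; rows dropped listwise = ",
           d$n_dropped),
    paste0("  Alpha      : ", format(x$spec$alpha)))
  if (any(d$centered)) {
    ms <- d$w_means[d$centered]
    lines <- c(lines, paste0("  Centering  : ",
      paste(sprintf("%s at mean %s", d$w_names[d$centered],
                    formatC(ms, digits = digits, format = "f")),
            collapse = "; "),
      " (zero is the sample average)"))
  }
  lines <- c(lines, "")

  lines <- c(lines, "Overall model (difference score)",
    if (is.finite(fit$r2))
      sprintf("  R-sq = %s,  F(%d, %d) = %s,  p = %s",
              formatC(fit$r2, digits = digits, format = "f"),
              fit$F$df1, fit$F$df2,
              formatC(fit$F$statistic, digits = digits, format = "f"),
              formatC(fit$F$p, digits = digits, format = "f"))
    else "  R-sq undefined (constant difference score)",
    "", "Coefficients",
    render_table(fit$table, digits), "")

  pick <- x$pick
  lines <- c(lines,
    "Conditional effect of condition ('X') on Y at values of the moderator(s)")
  if (any(d$centered))
    lines <- c(lines,
      "  (moderator values on the centered scale; add the stored mean for",
      "   the original scale)")
  lines <- c(lines, render_table(pick, digits), "")

  lines <- c(lines, "Conditional effect of moderator(s) on Y in each condition")
  cf <- x$cond_fits
  for (k in 1:2) {
    fk <- if (k == 1) cf$fit1 else cf$fit2
    tab <- fk$table[-1L, , drop = FALSE]  # moderator rows only
    lines <- c(lines,
      paste0("  Condition ", k, " (", d$y_names[k], "):"),
      render_table(tab, digits, indent = "    "))
  }
  lines <- c(lines, "")

  lines <- c(lines, "Johnson-Neyman procedure")
  if (is.character(x$jn)) {
    lines <- c(lines, paste0("  ", x$jn))
  } else {
    jn <- x$jn
    lines <- c(lines,
      sprintf("  critical t = %s at alpha = %s, df = %d",
              formatC(jn$t_crit, digits = digits, format = "f"),
              format(jn$alpha), fit$df),
      sprintf("  observed moderator range: %s to %s",
              formatC(jn$range[1], digits = digits, format = "f"),
              formatC(jn$range[2], digits = digits, format = "f")))
    if (!length(jn$roots)) {
      lines <- c(lines,
        "  no boundaries of significance inside the observed range")
    } else {
      bt <- data.frame(boundary = jn$roots, pct_above = jn$pct_above)
      if (d$centered[1])
        bt$boundary_original <- jn$roots + d$w_means[1]
      lines <- c(lines, "  Boundaries of significance:",
                 render_table(bt, digits, indent = "    "))
    }
    lines <- c(lines, "  Conditional effect of condition across the range:",
               render_table(jn$region_table, digits, indent = "    "))
  }
  lines
}

# Machine-readable mirror of the report for downstream tooling and tests.
report_json_payload <- function(x) {
  stopifnot(inherits(x, "rmmod"))
  d <- x$data; fit <- x$fit
  payload <- list(
    model = list(outcomes = d$y_names, moderators = d$w_names,
                 difference = paste(d$y_names, collapse = " - "),
                 type = x$spec$model, n = d$n, n_dropped = d$n_dropped,
                 alpha = x$spec$alpha,
                 centered = as.list(stats::setNames(d$centered, d$w_names)),
                 w_means = as.list(stats::setNames(d$w_means, d$w_names))),
    overall = list(r2 = fit$r2, F = fit$F$statistic, df1 = fit$F$df1,
                   df2 = fit$F$df2, p = fit$F$p),
    coefficients = fit$table,
    conditional_effects = x$pick,
    per_condition = list(condition1 = x$cond_fits$fit1$table,
                         condition2 = x$cond_fits$fit2$table))
  payload$johnson_neyman <- if (is.character(x$jn)) list(status = x$jn)
    else list(status = "computed", roots = x$jn$roots,
              pct_above = x$jn$pct_above, t_crit = x$jn$t_crit,
              region_table = x$jn$region_table)
  payload
}
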