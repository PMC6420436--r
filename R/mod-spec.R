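#' Specify a repeated-measures moderation model
#'
#' Collects the analysis options: how multiple moderators enter the model,
#' centering, the significance level, how the interaction is probed, and
#' whether the Johnson-Neyman procedure is requested.
#'
#' Additive moderation lets each moderator shift the condition effect without
#' interacting with the other moderators; multiplicative moderation adds all
#' products among moderators (so with two moderators the difference-score model
#' carries a three-way condition-by-W1-by-W2 interaction). With a single
#' moderator the two models coincide and the multiplicative path is used.
#'
#' @param model \code{"additive"} or \code{"multiplicative"} (the numeric
#'   codes 2 and 3 used by the command line are also accepted).
#' @param center Logical (or per-moderator logical vector): mean-center
#'   continuous moderators. Default \code{TRUE}.
#' @param alpha Significance level in (0, 1) for tests, intervals and the
#'   Johnson-Neyman critical t. Default 0.05.
#' @param probe \code{"meansd"} (moderator mean and mean +/- one SD, the
#'   default), \code{"percentile"} (16th, 50th, 84th percentiles), or
#'   \code{"custom"} (values supplied via \code{probe_values}).
#' @param probe_values For \code{probe = "custom"}: a list with one numeric
#'   vector of probe values per moderator, on the original (uncentered) scale.
#' @param jn Logical: compute Johnson-Neyman boundaries of significance
#'   (single continuous moderator only).
#' @param scheme Coding scheme for categorical moderators
#'   (\code{"indicator"} or \code{"helmert"}).
#' @return An object of class \code{"mod_spec"}.
#' @export
mod_spec <- function(model = c("multiplicative", "additive"),
                     center = TRUE, alpha = 0.05,
                     probe = c("meansd", "percentile", "custom"),
                     probe_values = NULL, jn = FALSE,
                     scheme = c("indicator", "helmert")) {
  if (is.numeric(model))
    model <- switch(as.character(model), "2" = "additive",
                    "3" = "multiplicative",
                    stop("model must be 2 (additive) or 3 (multiplicative)",
                         call. = FALSE))
  model <- match.arg(model)
  probe <- match.arg(probe)
  scheme <- match.arg(scheme)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single number in (0, 1)", call. = FALSE)
  if (probe == "custom") {
    if (is.null(probe_values))
      stop("probe = \"custom\" requires probe_values", call. = FALSE)
    if (!is.list(probe_values)) probe_values <- list(probe_values)
    if (!all(vapply(probe_values, function(v) all(is.finite(v)), logical(1))))
      stop("custom probe values must be finite", call. = FALSE)
  }
  structure(list(model = model, center = center, alpha = alpha,
                 probe = probe, probe_values = probe_values,
                 jn = isTRUE(jn), scheme = scheme),
            class = "mod_spec")
}
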