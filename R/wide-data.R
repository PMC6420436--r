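#' Construct a wide-form two-instance dataset
#'
#' Container for a two-instance repeated measures design in wide form: one row
#' per participant, with the outcome measured once in each instance (condition
#' or time point) and each between-participant moderator measured once.
#'
#' @param y1,y2 Numeric outcome vectors for the first- and second-listed
#'   instance. The difference score is always first-listed minus second-listed.
#' @param w A data frame of moderator columns (continuous numeric or factor /
#'   character categorical), one row per participant.
#' @param y_names Character vector of length 2 naming the two outcome columns
#'   (first-listed, second-listed).
#' @param w_names Character vector naming the moderator columns.
#' @param n_dropped Number of rows removed by listwise deletion before
#'   construction (recorded for reporting).
#'
#' @return An object of class \code{"wide_data"}: a list with elements
#'   \code{y1}, \code{y2}, \code{w}, \code{n}, \code{n_dropped},
#'   \code{y_names}, \code{w_names}, \code{w_cat} (logical: which moderators
#'   are categorical), \code{centered} (logical per moderator) and
#'   \code{w_means} (original sample means of centered columns, \code{NA}
#'   otherwise).
#' @seealso [read_wide_csv()], [make_difference()], [center_moderators()]
#' @export
wide_data <- function(y1, y2, w, y_names = c("y1", "y2"),
                      w_names = names(w), n_dropped = 0L) {
  if (!is.numeric(y1) || !is.numeric(y2))
    stop("outcome columns must be numeric", call. = FALSE)
  w <- as.data.frame(w)
  n <- length(y1)
  if (length(y2) != n || nrow(w) != n)
    stop("y1, y2 and moderator columns must have equal length", call. = FALSE)
  names(w) <- w_names
  w_cat <- vapply(w, is_categorical_column, logical(1))
  for (j in seq_along(w)) {
    if (length(unique(w[[j]])) < 2L)
      stop("moderator '", w_names[j],
           "' has fewer than 2 distinct values: design would be singular",
           call. = FALSE)
  }
  out <- list(y1 = as.numeric(y1), y2 = as.numeric(y2), w = w, n = n,
              n_dropped = as.integer(n_dropped),
              y_names = y_names, w_names = w_names, w_cat = w_cat,
              centered = rep(FALSE, length(w)),
              w_means = rep(NA_real_, length(w)))
  names(out$centered) <- names(out$w_means) <- w_names
  class(out) <- "wide_data"
  out
}

# Categorical if non-numeric; numeric columns (incl. 0/1 dummies) stay numeric
# and are never silently coerced.
is_categorical_column <- function(x) {
  is.factor(x) || is.character(x) || is.logical(x)
}

# Continuous for centering/probing purposes: numeric with > 2 distinct values.
# Numeric dichotomies (e.g. 0/1 group codes) are left on their original scale.
is_continuous_column <- function(x) {
  is.numeric(x) && length(unique(x)) > 2L
}

#' Read a wide-form CSV for two-instance moderation analysis
#'
#' Reads a comma-separated file with a header row, keeps the two named outcome
#' columns and the named moderator columns, and applies listwise deletion:
#' any row missing a value in any named column is dropped and the count of
#' dropped rows is recorded on the returned object.
#'
#' @param path Path to a CSV file (header row, '.' decimal separator, UTF-8).
#' @param y Character vector of length 2: the outcome column measured in the
#'   first and second instance, in the order the difference should be taken
#'   (first minus second).
#' @param w Character vector of moderator column names.
#' @return A [wide_data()] object.
#' @export
read_wide_csv <- function(path, y, w) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (length(y) != 2L)
    stop("exactly two outcome columns must be named (one per instance)",
         call. = FALSE)
  raw <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(c(y, w), names(raw))
  if (length(missing_cols))
    stop("column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  cols <- raw[, c(y, w), drop = FALSE]
  complete <- stats::complete.cases(cols)
  n_dropped <- sum(!complete)
  cols <- cols[complete, , drop = FALSE]
  # q counted on the additive scale; the multiplicative design can only be
  # larger, and its own rank check guards the rest.
  q_min <- length(w)
  if (nrow(cols) < q_min + 2L)
    stop("too few complete rows (", nrow(cols), ") for ", q_min,
         " moderator(s): need at least ", q_min + 2L, call. = FALSE)
  wide_data(cols[[y[1]]], cols[[y[2]]],
            cols[, w, drop = FALSE], y_names = y, w_names = w,
            n_dropped = n_dropped)
}

#' Difference score of the two instances
#'
#' Returns the within-person difference used as the regression response,
#' taken first-listed minus second-listed outcome. With outcomes listed
#' (pre, post), positive values mean the measure fell from the first to the
#' second instance.
#'
#' @param d A [wide_data()] object.
#' @return Numeric vector of length \code{d$n}.
#' @export
make_difference <- function(d) {
  stopifnot(inherits(d, "wide_data"))
  d$y1 - d$y2
}

#' Mean-center continuous moderators
#'
#' Centers each requested moderator at its sample mean so that zero is the
#' sample average, matching the usual convention for probing at "the mean".
#' Original means are stored on the object so probe values can be translated
#' between the original and the centered (analysis) scale. Categorical and
#' numeric-dichotomous columns are never centered.
#'
#' @param d A [wide_data()] object.
#' @param center Logical, or logical vector per moderator: which moderators to
#'   center. \code{TRUE} (default) centers every continuous moderator.
#' @return \code{d} with centered columns and the centering record filled in.
#' @export
center_moderators <- function(d, center = TRUE) {
  stopifnot(inherits(d, "wide_data"))
  m <- length(d$w)
  if (length(center) == 1L) center <- rep(center, m) & !d$w_cat
  if (length(center) != m)
    stop("'center' must be length 1 or one flag per moderator", call. = FALSE)
  for (j in seq_len(m)) {
    if (!center[j]) next
    if (d$w_cat[j])
      stop("cannot center categorical moderator '", d$w_names[j], "'",
           call. = FALSE)
    if (!is_continuous_column(d$w[[j]])) next  # numeric dichotomy: leave as-is
    mu <- mean(d$w[[j]])
    d$w[[j]] <- d$w[[j]] - mu
    d$centered[j] <- TRUE
    d$w_means[j] <- mu
  }
  d
}

#' Code a multicategorical moderator into k-1 columns
#'
#' A moderator with k unlabeled groups enters the model as a set of k-1
#' numeric columns. Indicator (dummy) coding uses the first category in sorted
#' label order as the reference (all-zero row); Helmert coding contrasts each
#' category with the mean of the preceding ones, each column summing to zero
#' over the category set.
#'
#' @param x A factor or character vector with k >= 2 levels.
#' @param scheme \code{"indicator"} or \code{"helmert"}.
#' @return Numeric matrix with k-1 named columns, one row per element of
#'   \code{x}.
#' @export
encode_multicategorical <- function(x, scheme = c("indicator", "helmert")) {
  scheme <- match.arg(scheme)
  f <- factor(x)  # levels sorted by label
  k <- nlevels(f)
  if (k < 2L)
    stop("moderator has a single category; no contrast is possible",
         call. = FALSE)
  contr <- switch(scheme,
                  indicator = stats::contr.treatment(k),
                  helmert   = stats::contr.helmert(k))
  m <- contr[as.integer(f), , drop = FALSE]
  colnames(m) <- switch(scheme,
                        indicator = levels(f)[-1L],
                        helmert   = paste0("H", seq_len(k - 1L)))
  rownames(m) <- NULL
  m
}

# Expand every categorical moderator column into its coded numeric columns,
# returning a new wide_data whose moderators are all numeric. Coded columns
# are flagged so they are never centered or probed as continuous.
expand_categorical <- function(d, scheme = "indicator") {
  if (!any(d$w_cat)) return(d)
  new_w <- list()
  for (j in seq_along(d$w)) {
    if (!d$w_cat[j]) {
      new_w[[d$w_names[j]]] <- d$w[[j]]
    } else {
      coded <- encode_multicategorical(d$w[[j]], scheme)
      for (cn in colnames(coded))
        new_w[[paste0(d$w_names[j], ".", cn)]] <- coded[, cn]
    }
  }
  out <- wide_data(d$y1, d$y2, as.data.frame(new_w),
                   y_names = d$y_names, w_names = names(new_w),
                   n_dropped = d$n_dropped)
  out
}

#' @export
print.wide_data <- function(x, ...) {
  cat("Two-instance wide-form dataset\n")
  cat("  outcomes   :", paste(x$y_names, collapse = ", "),
      "(difference =", x$y_names[1], "-", paste0(x$y_names[2], ")\n"))
  cat("  moderators :", paste(x$w_names, collapse = ", "), "\n")
  cat("  n =", x$n, "complete rows;", x$n_dropped, "dropped (listwise)\n")
  invisible(x)
}
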