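#' Build a 2x2 contingency table from a test and a condition
#'
#' Crosses a binary screening result against a binary reference condition
#' and counts true positives, false positives, false negatives, and true
#' negatives.
#'
#' @param test_positive Logical vector; `TRUE` = screen positive.
#' @param condition_positive Logical vector of equal length; `TRUE` =
#'   condition present by the reference standard.
#' @return An object of class `ctab2x2` (see [ctab2x2()]).
#' @export
crosstab <- function(test_positive, condition_positive) {
  if (length(test_positive) != length(condition_positive)) {
    stop("test and condition vectors differ in length", call. = FALSE)
  }
  if (length(test_positive) < 1L) stop("empty vectors", call. = FALSE)
  if (anyNA(test_positive) || anyNA(condition_positive)) {
    stop("missing values in test or condition vector", call. = FALSE)
  }
  t <- as.logical(test_positive); c <- as.logical(condition_positive)
  ctab2x2(tp = sum(t & c), fp = sum(t & !c), fn = sum(!t & c),
          tn = sum(!t & !c))
}

#' Construct a 2x2 contingency table from counts
#'
#' @param tp,fp,fn,tn Nonnegative integer counts: test-positive with and
#'   without the condition, test-negative with and without the condition.
#' @return A list of class `ctab2x2` with the four counts and total `n`.
#' @export
ctab2x2 <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("table total must be positive", call. = FALSE)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 n = as.integer(sum(counts))),
            class = "ctab2x2")
}

#' @export
print.ctab2x2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, byrow = TRUE,
              dimnames = list(test = c("positive", "negative"),
                              condition = c("positive", "negative")))
  print(m)
  invisible(x)
}

as_matrix_ctab <- function(tab) {
  matrix(c(tab$tp, tab$fp, tab$fn, tab$tn), nrow = 2, byrow = TRUE)
}

# Ratio with an explicit undefined (NA) on a zero denominator; metrics are
# never silently coerced to 0.
safe_prop <- function(num, den) if (den == 0) NA_real_ else num / den

#' Diagnostic accuracy metrics from a 2x2 table
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), positive predictive
#' value tp/(tp+fp), negative predictive value tn/(tn+fn), and the Youden
#' index (Se + Sp - 1). Metrics with a zero denominator are returned as
#' `NA` and listed in `undefined`. Wilson score intervals accompany each
#' defined proportion; the underlying counts are kept so report renderings
#' stay traceable.
#'
#' @param table A [ctab2x2()].
#' @param level Confidence level for the Wilson intervals (default 0.95).
#' @return A list of class `diag_summary`: proportions `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `youden`, a `ci` list per metric, the
#'   source `table`, and `undefined` (character vector of flagged metrics).
#' @examples
#' diag_metrics(ctab2x2(16, 9, 4, 73))
#' @export
diag_metrics <- function(table, level = 0.95) {
  stopifnot(inherits(table, "ctab2x2"))
  t <- table
  parts <- list(
    sensitivity = c(t$tp, t$tp + t$fn),
    specificity = c(t$tn, t$tn + t$fp),
    ppv         = c(t$tp, t$tp + t$fp),
    npv         = c(t$tn, t$tn + t$fn))
  est <- lapply(parts, function(p) safe_prop(p[1], p[2]))
  ci <- lapply(parts, function(p) {
    if (p[2] == 0) c(lower = NA_real_, upper = NA_real_)
    else wilson_ci(p[1], p[2], level)
  })
  youden <- if (is.na(est$sensitivity) || is.na(est$specificity)) NA_real_
            else est$sensitivity + est$specificity - 1
  undefined <- names(est)[vapply(est, is.na, logical(1))]
  if (is.na(youden)) undefined <- c(undefined, "youden")
  structure(c(est, list(youden = youden, ci = ci, level = level,
                        table = t, undefined = undefined)),
            class = "diag_summary")
}

#' @export
print.diag_summary <- function(x, digits = 3, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.0f%%", 100 * v)
  cat(sprintf("Se %s  Sp %s  PPV %s  NPV %s  Youden %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv), fmt(x$npv),
              if (is.na(x$youden)) "undefined" else sprintf("%.2f", x$youden)))
  invisible(x)
}

#' Risk ratio from a 2x2 table
#'
#' Risk of the condition among test-positives over the risk among
#' test-negatives: (tp/(tp+fp)) / (fn/(fn+tn)). When no test-negative has
#' the condition (fn = 0) while test-positives do, the ratio is flagged
#' infinite; when there are no test-positives it is undefined (`NA`).
#'
#' @param table A [ctab2x2()].
#' @return A single numeric value; `Inf` or `NA` in the degenerate cases.
#' @examples
#' risk_ratio(ctab2x2(16, 9, 4, 73))  # 12.32
#' @export
risk_ratio <- function(table) {
  stopifnot(inherits(table, "ctab2x2"))
  t <- table
  if (t$tp + t$fp == 0) return(NA_real_)
  if (t$fn + t$tn == 0) return(NA_real_)
  risk_pos <- t$tp / (t$tp + t$fp)
  risk_neg <- t$fn / (t$fn + t$tn)
  if (risk_neg == 0) {
    if (risk_pos > 0) return(Inf)
    return(NA_real_)  # 0/0: no information
  }
  risk_pos / risk_neg
}

#' Katz log-method confidence interval for a risk ratio
#'
#' exp(log RR +/- z * sqrt(1/tp - 1/(tp+fp) + 1/fn - 1/(fn+tn))). Requires
#' all four cells positive; with a zero cell the interval is undefined and
#' returned as `NA` (no continuity correction is applied by default).
#'
#' @param table A [ctab2x2()].
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
rr_ci <- function(table, level = 0.95) {
  stopifnot(inherits(table, "ctab2x2"), level > 0, level < 1)
  t <- table
  if (min(t$tp, t$fp, t$fn, t$tn) == 0) {
    return(c(lower = NA_real_, upper = NA_real_))
  }
  rr <- risk_ratio(t)
  se_log <- sqrt(1 / t$tp - 1 / (t$tp + t$fp) + 1 / t$fn - 1 / (t$fn + t$tn))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(lower = rr * exp(-z * se_log), upper = rr * exp(z * se_log))
}

#' Wilson score interval for a binomial proportion
#'
#' @param successes,trials Integer counts, 0 <= successes <= trials,
#'   trials >= 1.
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`, contained in [0, 1]
#'   and containing the point estimate.
#' @export
wilson_ci <- function(successes, trials, level = 0.95) {
  if (trials < 1 || successes < 0 || successes > trials) {
    stop("need 0 <= successes <= trials with trials >= 1", call. = FALSE)
  }
  stopifnot(level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / trials
  denom <- 1 + z^2 / trials
  center <- (p + z^2 / (2 * trials)) / denom
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Two-sided association test for a 2x2 table
#'
#' Uses Fisher's exact test (two-sided by the point-probability rule)
#' whenever any expected cell count is below 5, and the chi-square test
#' with Yates continuity correction otherwise. The method actually applied
#' is recorded alongside the p-value. Degenerate tables (a zero row or
#' column margin) carry no information about association and return p = 1
#' with a flag.
#'
#' @param table A [ctab2x2()].
#' @return List with `p_value`, `method` (`"fisher"` or `"chisq_yates"`),
#'   and `degenerate` (logical).
#' @examples
#' association_p(ctab2x2(4, 2, 16, 80))    # Fisher, p = 0.013
#' association_p(ctab2x2(19, 16, 17, 50))  # Yates chi-square, p = 0.007
#' @export
association_p <- function(table) {
  stopifnot(inherits(table, "ctab2x2"))
  m <- as_matrix_ctab(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(list(p_value = 1, method = "degenerate", degenerate = TRUE))
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    p <- stats::fisher.test(m)$p.value
    method <- "fisher"
  } else {
    p <- suppressWarnings(stats::chisq.test(m, correct = TRUE)$p.value)
    method <- "chisq_yates"
  }
  list(p_value = min(1, p), method = method, degenerate = FALSE)
}
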