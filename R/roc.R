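#' Score-by-group distribution of an integer test score
#'
#' Holds, for every integer score value, the number of condition-positive
#' and condition-negative patients at that score. This is the sufficient
#' statistic for the empirical ROC curve of an integer-valued scale.
#'
#' @param scores Integer vector of per-patient scores, or `NULL` when
#'   `pos`/`neg` counts are given directly.
#' @param condition Logical vector parallel to `scores`.
#' @param pos,neg Alternative construction: named or plain integer count
#'   vectors over consecutive scores `score_values`.
#' @param score_values Integer vector of score values matching `pos`/`neg`.
#' @return A list of class `score_distribution` with `scores`, `pos`,
#'   `neg`, `n_pos`, `n_neg`.
#' @export
score_distribution <- function(scores = NULL, condition = NULL,
                               pos = NULL, neg = NULL, score_values = NULL) {
  if (!is.null(scores)) {
    stopifnot(length(scores) == length(condition),
              !anyNA(scores), !anyNA(condition))
    condition <- as.logical(condition)
    rng <- range(scores)
    score_values <- seq.int(min(0L, rng[1]), rng[2])
    pos <- tabulate(match(scores[condition], score_values),
                    nbins = length(score_values))
    neg <- tabulate(match(scores[!condition], score_values),
                    nbins = length(score_values))
  } else {
    stopifnot(length(pos) == length(neg), length(pos) == length(score_values))
    stopifnot(all(pos >= 0), all(neg >= 0))
  }
  out <- list(scores = as.integer(score_values),
              pos = as.integer(pos), neg = as.integer(neg),
              n_pos = as.integer(sum(pos)), n_neg = as.integer(sum(neg)))
  class(out) <- "score_distribution"
  out
}

#' @export
print.score_distribution <- function(x, ...) {
  df <- data.frame(score = x$scores, condition_pos = x$pos,
                   condition_neg = x$neg)
  cat(sprintf("score distribution: %d condition-positive, %d condition-negative\n",
              x$n_pos, x$n_neg))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Operating characteristics at every integer cut-point
#'
#' For each cut-point c the test is positive iff score >= c. Rows run from
#' the minimum score (everyone positive: Se = 1, Sp = 0) to one above the
#' maximum score (nobody positive: Se = 0, Sp = 1), so the trivial ROC
#' endpoints are always present.
#'
#' @param distribution A [score_distribution()] with both groups nonempty.
#' @return Data frame of class `roc_curve` with columns `cutpoint`, `tp`,
#'   `fp`, `se`, `sp`, `one_minus_sp`, `youden`, `ppv`, `npv`.
#' @export
cutpoint_table <- function(distribution) {
  stopifnot(inherits(distribution, "score_distribution"))
  d <- distribution
  if (d$n_pos < 1 || d$n_neg < 1) {
    stop("both condition groups must be nonempty", call. = FALSE)
  }
  cuts <- c(d$scores, max(d$scores) + 1L)
  rows <- lapply(cuts, function(c) {
    at_or_above <- d$scores >= c
    tp <- sum(d$pos[at_or_above]); fp <- sum(d$neg[at_or_above])
    fn <- d$n_pos - tp;            tn <- d$n_neg - fp
    se <- tp / d$n_pos; sp <- tn / d$n_neg
    data.frame(cutpoint = c, tp = tp, fp = fp, se = se, sp = sp,
               one_minus_sp = 1 - sp, youden = se + sp - 1,
               ppv = safe_prop(tp, tp + fp), npv = safe_prop(tn, tn + fn))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("roc_curve", "data.frame")
  attr(out, "n_pos") <- d$n_pos
  attr(out, "n_neg") <- d$n_neg
  out
}

# AUC by the tie-corrected rank statistic: P(score_pos > score_neg) +
# 0.5 * P(score_pos = score_neg), computed from group counts.
auc_rank <- function(d) {
  total <- as.numeric(d$n_pos) * d$n_neg
  neg_below <- cumsum(c(0, d$neg))[seq_along(d$neg)]
  (sum(d$pos * neg_below) + 0.5 * sum(d$pos * d$neg)) / total
}

# AUC by the trapezoidal rule over the empirical ROC polygon.
auc_trapezoid <- function(d) {
  curve <- cutpoint_table(d)
  fpr <- rev(curve$one_minus_sp)  # ascending in 1-Sp
  tpr <- rev(curve$se)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Area under the empirical ROC curve
#'
#' Computes the tie-corrected rank form P(score_pos > score_neg) +
#' 1/2 P(equal) and the trapezoidal area under the empirical ROC polygon,
#' asserts they agree to 1e-12 (they are mathematically identical on
#' empirical data; the dual computation guards against off-by-one
#' cut-point bugs), and returns the value.
#'
#' @param distribution A [score_distribution()] with both groups nonempty.
#' @return AUC in [0, 1].
#' @export
auc <- function(distribution) {
  stopifnot(inherits(distribution, "score_distribution"))
  d <- distribution
  if (d$n_pos < 1 || d$n_neg < 1) {
    stop("both condition groups must be nonempty", call. = FALSE)
  }
  a_rank <- auc_rank(d)
  a_trap <- auc_trapezoid(d)
  if (abs(a_rank - a_trap) > 1e-12) {
    stop(sprintf("internal AUC disagreement: rank %.15f vs trapezoid %.15f",
                 a_rank, a_trap))
  }
  a_rank
}

#' Optimal cut-point by the Youden index
#'
#' Returns the cut-point maximizing Se + Sp - 1 among informative
#' cut-points (those with at least one patient at or above the cut and at
#' least one below). Ties are broken toward the lowest cut-point, favoring
#' sensitivity — the natural choice for a screening instrument.
#'
#' @param curve A `roc_curve` from [cutpoint_table()].
#' @return The selected integer cut-point.
#' @export
optimal_cutpoint <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"), nrow(curve) > 0)
  informative <- curve[curve$se < 1 | curve$sp > 0, , drop = FALSE]
  informative <- informative[informative$se > 0 | informative$sp < 1, ,
                             drop = FALSE]
  if (nrow(informative) == 0) informative <- curve
  informative$cutpoint[which.max(informative$youden)]
}

#' Reconstruct a score-by-group distribution from cumulative ROC rows
#'
#' Published ROC tables report, at each integer cut-point c, the cumulative
#' sensitivity (fraction of condition-positives scoring >= c) and
#' 1 - specificity (fraction of condition-negatives scoring >= c). Given
#' the group sizes, these scale back to patient counts; differencing
#' adjacent cut-points recovers the per-score counts. Scores at or above
#' the last cut-point are collapsed onto that cut-point's value. Each
#' scaled cumulative count must land within `tol` of an integer, otherwise
#' the offending row is reported — a guard against mistranscribed tables.
#'
#' @param cumulative_rows Data frame with columns `cutpoint` (consecutive
#'   integers), `se`, `one_minus_sp` (non-increasing fractions).
#' @param n_pos,n_neg Group sizes.
#' @param tol Maximum allowed distance from an integer for each scaled
#'   count, in patients (default 0.02).
#' @return A [score_distribution()] over scores `0 .. max(cutpoint)`.
#' @examples
#' reconstruct_distribution(table9_rows(), n_pos = 20, n_neg = 82)
#' @export
reconstruct_distribution <- function(cumulative_rows, n_pos, n_neg,
                                     tol = 0.02) {
  stopifnot(is.data.frame(cumulative_rows),
            all(c("cutpoint", "se", "one_minus_sp") %in% names(cumulative_rows)),
            n_pos >= 1, n_neg >= 1)
  rows <- cumulative_rows[order(cumulative_rows$cutpoint), , drop = FALSE]
  if (!all(diff(rows$cutpoint) == 1)) {
    stop("cutpoints must be consecutive integers", call. = FALSE)
  }
  if (any(diff(rows$se) > 1e-12) || any(diff(rows$one_minus_sp) > 1e-12)) {
    stop("cumulative fractions must be non-increasing in the cutpoint",
         call. = FALSE)
  }
  snap_counts <- function(frac, n, what) {
    raw <- frac * n
    snapped <- round(raw)
    off <- abs(raw - snapped)
    if (any(off >= tol)) {
      i <- which.max(off)
      stop(sprintf(
        "row with cutpoint %d: cumulative %s count %.4f is %.4f patients from an integer",
        rows$cutpoint[i], what, raw[i], off[i]), call. = FALSE)
    }
    snapped
  }
  cum_pos <- snap_counts(rows$se, n_pos, "condition-positive")
  cum_neg <- snap_counts(rows$one_minus_sp, n_neg, "condition-negative")
  # counts >= c for c = cutpoints, then 0 beyond the last cutpoint
  per_score_pos <- -diff(c(cum_pos, 0))
  per_score_neg <- -diff(c(cum_neg, 0))
  first <- rows$cutpoint[1]
  scores <- seq.int(first - 1L, max(rows$cutpoint))
  pos <- c(n_pos - cum_pos[1], per_score_pos)
  neg <- c(n_neg - cum_neg[1], per_score_neg)
  if (first > 1L) {  # pad down to score 0; mass below the first cut stays at first-1
    scores <- c(seq.int(0L, first - 2L), scores)
    pos <- c(rep(0L, first - 1L), pos)
    neg <- c(rep(0L, first - 1L), neg)
  }
  score_distribution(pos = pos, neg = neg, score_values = scores)
}
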