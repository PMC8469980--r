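# Independent oracles, kept deliberately naive and separate from the
# implementation paths they check.

# Two-sided Fisher p by exhaustive hypergeometric enumeration over all
# tables with the observed margins (point-probability rule: sum the
# probabilities of tables no more likely than the observed one).
fisher_enumeration_p <- function(tp, fp, fn, tn) {
  m <- tp + fn          # condition-positive margin
  n <- fp + tn          # condition-negative margin
  k <- tp + fp          # test-positive margin
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tp, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# AUC by explicit materialization: expand a score distribution to patient
# lists and compare every positive/negative pair.
auc_bruteforce <- function(dist) {
  pos <- rep(dist$scores, dist$pos)
  neg <- rep(dist$scores, dist$neg)
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# 2x2 metrics by materializing the patients and counting directly.
metrics_bruteforce <- function(tab) {
  test <- c(rep(TRUE, tab$tp + tab$fp), rep(FALSE, tab$fn + tab$tn))
  cond <- c(rep(TRUE, tab$tp), rep(FALSE, tab$fp),
            rep(TRUE, tab$fn), rep(FALSE, tab$tn))
  list(se = mean(test[cond]), sp = mean(!test[!cond]),
       ppv = mean(cond[test]), npv = mean(!cond[!test]))
}

# Closed-form phi coefficient for a 2x2 table (a=tp, b=fp, c=fn, d=tn
# crossing test x condition).
phi_closed_form <- function(a, b, c, d) {
  (a * d - b * c) / sqrt((a + b) * (c + d) * (a + c) * (b + d))
}

# Random small score distribution for property tests.
random_distribution <- function(max_score = 5) {
  repeat {
    pos <- stats::rpois(max_score + 1, 1.2)
    neg <- stats::rpois(max_score + 1, 1.2)
    if (sum(pos) > 0 && sum(neg) > 0) break
  }
  score_distribution(pos = pos, neg = neg, score_values = 0:max_score)
}

# Tiny complete dual-scale cohort built by hand.
tiny_cohort <- function() {
  cohort <- data.frame(patient_id = c("a", "b", "c", "d"))
  for (it in zfs_items()) cohort[[paste0("zfs_", it)]] <- c(0L, 1L, 0L, 1L)
  cohort$zfs_weight_loss <- c(0L, 0L, 1L, 1L)
  for (it in msega_items()) cohort[[paste0("msega_", it)]] <- c(0L, 1L, 0L, 2L)
  cohort$msega_mobility <- c(0L, 2L, 1L, 2L)
  cohort
}
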