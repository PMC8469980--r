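t9_dist <- reconstruct_distribution(table9_rows(), n_pos = 20, n_neg = 82)

test_that("reconstruction from the published cumulative rows recovers the per-score counts", {
  expect_equal(t9_dist$scores, 0:5)
  expect_equal(t9_dist$pos, c(0, 0, 0, 7, 10, 3))
  expect_equal(t9_dist$neg, c(15, 17, 34, 12, 3, 1))
  expect_equal(t9_dist$n_pos + t9_dist$n_neg, 102)
})

test_that("reconstruction rejects non-monotone rows and non-integer scaled counts", {
  rows <- table9_rows()
  rows$se[5] <- 0.70  # se would increase from cutpoint 4 to 5
  expect_error(reconstruct_distribution(rows, 20, 82), "non-increasing")

  rows2 <- table9_rows()
  rows2$one_minus_sp[3] <- 0.20  # 0.20 * 82 = 16.4, a non-integer count
  expect_error(reconstruct_distribution(rows2, 20, 82), "cutpoint 3")

  one_row <- data.frame(cutpoint = 1, se = 1, one_minus_sp = 1)
  d <- reconstruct_distribution(one_row, 1, 1)
  expect_equal(d$pos, c(0, 1))  # everyone scored >= 1
  expect_equal(d$neg, c(0, 1))
})

test_that("round trip: the cut-point table of the reconstruction reproduces the published rows", {
  curve <- cutpoint_table(t9_dist)
  rows <- table9_rows()
  for (i in seq_len(nrow(rows))) {
    row <- curve[curve$cutpoint == rows$cutpoint[i], ]
    expect_lt(abs(row$se - rows$se[i]), 5e-3)            # printed to 2 decimals
    expect_lt(abs(row$one_minus_sp - rows$one_minus_sp[i]), 5e-5)  # printed to 4
  }
  # printed operating characteristics at the frailty cut-point
  at3 <- curve[curve$cutpoint == 3, ]
  expect_equal(at3$se, 1.000)
  expect_equal(round(at3$sp, 2), 0.80)
  expect_equal(round(at3$youden, 2), 0.80)
  expect_equal(round(at3$ppv, 2), 0.56)
  expect_equal(at3$npv, 1.000)
})

test_that("cut-point rows equal brute-force metrics from materialized patients", {
  set.seed(23)
  for (i in 1:20) {
    d <- random_distribution()
    curve <- cutpoint_table(d)
    for (c in curve$cutpoint) {
      pos <- rep(d$scores, d$pos); neg <- rep(d$scores, d$neg)
      tab <- crosstab(c(pos, neg) >= c,
                      c(rep(TRUE, length(pos)), rep(FALSE, length(neg))))
      row <- curve[curve$cutpoint == c, ]
      expect_equal(row$se, tab$tp / d$n_pos)
      expect_equal(row$sp, tab$tn / d$n_neg)
    }
  }
})

test_that("ROC curves are monotone: se non-increasing, sp non-decreasing in the cut-point", {
  set.seed(29)
  for (i in 1:50) {
    curve <- cutpoint_table(random_distribution())
    expect_true(all(diff(curve$se) <= 1e-12))
    expect_true(all(diff(curve$sp) >= -1e-12))
  }
})

test_that("AUC: published value, trivial cases, and brute-force equivalence", {
  expect_equal(round(auc(t9_dist), 5), 0.94116)

  same <- score_distribution(pos = c(3, 2, 1), neg = c(6, 4, 2),
                             score_values = 0:2)
  expect_equal(auc(same), 0.5)

  two <- score_distribution(pos = c(0, 1), neg = c(1, 0), score_values = 0:1)
  expect_equal(auc(two), 1.0)

  set.seed(37)
  for (i in 1:40) {
    d <- random_distribution()
    expect_equal(auc(d), auc_bruteforce(d), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC package on the reconstructed data", {
  skip_if_not_installed("pROC")
  scores <- rep(t9_dist$scores, t9_dist$pos + t9_dist$neg)
  labels <- c(rep(1, 0), unlist(mapply(function(s, p, n) c(rep(1, p), rep(0, n)),
                                       t9_dist$scores, t9_dist$pos, t9_dist$neg)))
  r <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(as.numeric(pROC::auc(r)), auc(t9_dist), tolerance = 1e-12)
})

test_that("optimal cut-point maximizes Youden with ties broken low", {
  expect_equal(optimal_cutpoint(cutpoint_table(t9_dist)), 3)

  perfect <- score_distribution(pos = c(0, 0, 2), neg = c(3, 1, 0),
                                score_values = 0:2)
  expect_equal(optimal_cutpoint(cutpoint_table(perfect)), 2)

  # flat curve: identical score distributions give constant youden = 0
  flat <- score_distribution(pos = c(2, 2, 2), neg = c(4, 4, 4),
                             score_values = 0:2)
  curve <- cutpoint_table(flat)
  expect_equal(optimal_cutpoint(curve), min(curve$cutpoint[curve$se < 1 | curve$sp > 0]))
})

test_that("distributions require both groups nonempty", {
  empty_pos <- score_distribution(pos = c(0, 0), neg = c(2, 3),
                                  score_values = 0:1)
  expect_error(cutpoint_table(empty_pos), "nonempty")
  expect_error(auc(empty_pos), "nonempty")
})

test_that("reconstructed cohort matches the published score summary and group sizes", {
  all_scores <- rep(t9_dist$scores, t9_dist$pos + t9_dist$neg)
  expect_equal(round(mean(all_scores), 1), 2.1)
  expect_equal(round(stats::sd(all_scores), 2), 1.35)
  expect_equal(t9_dist$n_pos, 20)
  expect_equal(t9_dist$n_neg, 82)
  expect_equal(t9_dist$n_pos / 102, 0.196, tolerance = 1e-3)
})
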