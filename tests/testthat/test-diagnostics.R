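test_that("crosstab partitions the cohort into the four cells", {
  t <- crosstab(TRUE, TRUE)
  expect_equal(c(t$tp, t$fp, t$fn, t$tn), c(1, 0, 0, 0))

  set.seed(5)
  v <- sample(c(TRUE, FALSE), 30, replace = TRUE)
  t <- crosstab(v, v)
  expect_equal(t$fp, 0)
  expect_equal(t$fn, 0)
  expect_equal(t$n, 30)

  expect_error(crosstab(c(TRUE, FALSE), TRUE), "length")
  expect_error(crosstab(c(TRUE, NA), c(TRUE, FALSE)), "missing")
})

test_that("diagnostic metrics reproduce the published aid-at-home and balance items", {
  m <- diag_metrics(ctab2x2(16, 9, 4, 73))
  expect_equal(m$sensitivity, 0.80)
  expect_equal(m$specificity, 73 / 82, tolerance = 1e-12)
  expect_equal(m$ppv, 0.64)
  expect_equal(m$npv, 73 / 77, tolerance = 1e-12)
  expect_equal(round(m$specificity, 2), 0.89)
  expect_equal(round(m$npv, 2), 0.95)

  m2 <- diag_metrics(ctab2x2(17, 38, 3, 44))
  expect_equal(m2$sensitivity, 0.85)
  expect_equal(round(m2$specificity, 2), 0.54)
  expect_equal(round(m2$ppv, 2), 0.31)
  expect_equal(round(m2$npv, 2), 0.94)
})

test_that("metrics match brute-force counting on random tables and stay in range", {
  set.seed(31)
  for (i in 1:50) {
    counts <- rpois(4, 6) + c(1, 1, 1, 1)  # all cells positive
    tab <- ctab2x2(counts[1], counts[2], counts[3], counts[4])
    m <- diag_metrics(tab)
    bf <- metrics_bruteforce(tab)
    expect_equal(m$sensitivity, bf$se)
    expect_equal(m$specificity, bf$sp)
    expect_equal(m$ppv, bf$ppv)
    expect_equal(m$npv, bf$npv)
    expect_true(all(unlist(m[c("sensitivity", "specificity", "ppv", "npv")]) >= 0))
    expect_true(all(unlist(m[c("sensitivity", "specificity", "ppv", "npv")]) <= 1))
    expect_gte(m$youden, -1); expect_lte(m$youden, 1)
  }
})

test_that("zero-denominator metrics are flagged undefined, never silently 0", {
  m <- diag_metrics(ctab2x2(0, 0, 5, 7))
  expect_equal(m$sensitivity, 0)
  expect_true(is.na(m$ppv))
  expect_true("ppv" %in% m$undefined)
})

test_that("risk ratios reproduce the six published values", {
  tabs <- table8_contingencies()
  printed <- c(weight_loss = 4.00, monopodal = 4.84, lives_alone = 2.35,
               home_aid = 12.32, memory = 2.34, polypharmacy = 3.65)
  for (nm in names(printed)) {
    expect_equal(risk_ratio(tabs[[nm]]), printed[[nm]], tolerance = 0.005 / printed[[nm]])
  }
})

test_that("risk ratio handles degenerate tables and satisfies reciprocal symmetry", {
  expect_equal(risk_ratio(ctab2x2(2, 2, 1, 1)), 1.0)
  expect_true(is.infinite(risk_ratio(ctab2x2(3, 4, 0, 5))))
  expect_true(is.na(risk_ratio(ctab2x2(0, 0, 3, 4))))

  set.seed(13)
  for (i in 1:30) {
    x <- rpois(4, 8) + 1
    rr_fwd <- risk_ratio(ctab2x2(x[1], x[2], x[3], x[4]))
    rr_swp <- risk_ratio(ctab2x2(x[3], x[4], x[1], x[2]))
    expect_equal(rr_fwd * rr_swp, 1, tolerance = 1e-12)
  }
})

test_that("Katz interval contains the point risk ratio and is undefined on zero cells", {
  ci <- rr_ci(ctab2x2(16, 9, 4, 73))
  expect_lt(ci[["lower"]], 12.32)
  expect_gt(ci[["upper"]], 12.32)

  ci1 <- rr_ci(ctab2x2(1, 1, 1, 1))
  expect_lt(ci1[["lower"]], 1); expect_gt(ci1[["upper"]], 1)

  expect_true(all(is.na(rr_ci(ctab2x2(0, 3, 2, 5)))))
})

test_that("Katz interval for the aid item agrees with a seeded bootstrap", {
  # resample 102 patients from the aid-at-home table; the analytic interval
  # should roughly bracket the central 95% of resampled risk ratios
  tab <- ctab2x2(16, 9, 4, 73)
  cell <- c(rep(1, 16), rep(2, 9), rep(3, 4), rep(4, 73))
  set.seed(202109)
  rrs <- replicate(1e4, {
    s <- table(factor(sample(cell, length(cell), replace = TRUE), 1:4))
    if (s[1] + s[2] == 0 || s[3] + s[4] == 0 || s[3] == 0) NA_real_
    else (s[[1]] / (s[[1]] + s[[2]])) / (s[[3]] / (s[[3]] + s[[4]]))
  })
  q <- stats::quantile(rrs, c(0.025, 0.975), na.rm = TRUE)
  ci <- rr_ci(tab)
  expect_equal(log(ci[["lower"]]), log(q[[1]]), tolerance = 0.15)
  expect_equal(log(ci[["upper"]]), log(q[[2]]), tolerance = 0.15)
})

test_that("Wilson interval brackets the estimate and is checked against Clopper-Pearson", {
  expect_equal(wilson_ci(0, 10)[["lower"]], 0)
  expect_equal(wilson_ci(10, 10)[["upper"]], 1)

  ci <- wilson_ci(17, 20, 0.95)
  expect_lt(ci[["lower"]], 17 / 20); expect_gt(ci[["upper"]], 17 / 20)
  # exact Clopper-Pearson bounds (beta quantiles over the binomial tail)
  cp <- c(stats::qbeta(0.025, 17, 4), stats::qbeta(0.975, 18, 3))
  expect_lt(abs(ci[["lower"]] - cp[1]), 0.05)
  expect_lt(abs(ci[["upper"]] - cp[2]), 0.05)
  # Wilson is contained in [0,1] on random cases and CP brackets it loosely
  set.seed(99)
  for (i in 1:25) {
    n <- sample(5:60, 1); x <- sample(0:n, 1)
    w <- wilson_ci(x, n)
    expect_gte(w[["lower"]], 0); expect_lte(w[["upper"]], 1)
    expect_lte(w[["lower"]], x / n + 1e-12); expect_gte(w[["upper"]], x / n - 1e-12)
  }
  expect_error(wilson_ci(5, 3), "successes")
})

test_that("association test reproduces the published p-values with the stated methods", {
  fisher_row <- association_p(ctab2x2(4, 2, 16, 80))
  expect_equal(fisher_row$method, "fisher")
  expect_equal(round(fisher_row$p_value, 3), 0.013)

  chisq_row <- association_p(ctab2x2(19, 16, 17, 50))
  expect_equal(chisq_row$method, "chisq_yates")
  expect_equal(round(chisq_row$p_value, 3), 0.007)

  indep <- association_p(ctab2x2(5, 5, 5, 5))
  expect_equal(indep$p_value, 1.0)

  degen <- association_p(ctab2x2(0, 0, 3, 4))
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 1)
})

test_that("Fisher p matches exhaustive hypergeometric enumeration on small tables", {
  set.seed(17)
  for (i in 1:40) {
    counts <- as.vector(stats::rmultinom(1, sample(8:60, 1), rep(0.25, 4)))
    m <- matrix(counts, 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    p_impl <- stats::fisher.test(m)$p.value
    p_enum <- fisher_enumeration_p(counts[1], counts[3], counts[2], counts[4])
    expect_equal(p_impl, p_enum, tolerance = 1e-9)
  }
})
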