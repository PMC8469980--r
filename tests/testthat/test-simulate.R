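test_that("calibrated thresholds invert the normal tail", {
  expect_equal(calibrate_threshold(0.5), 0)
  expect_equal(calibrate_threshold(0.44), 0.1509692, tolerance = 1e-6)
  for (p in c(0.05, 0.2, 0.44, 0.9)) {
    expect_equal(calibrate_threshold(p), -calibrate_threshold(1 - p),
                 tolerance = 1e-12)
    expect_equal(1 - stats::pnorm(calibrate_threshold(p)), p, tolerance = 1e-12)
  }
  expect_error(calibrate_threshold(0), "prevalence")
  expect_error(calibrate_threshold(1), "prevalence")
})

test_that("invalid specifications are rejected before sampling", {
  expect_error(default_spec(n = 0), "cohort size")
  spec <- default_spec()
  spec$items[[1]]$loading <- 1.2
  expect_error(validate_sim_spec(spec), "loading")
  spec2 <- default_spec()
  spec2$items[[7]]$probs <- c(0.5, 0.5, 0.5)
  expect_error(validate_sim_spec(spec2), "summing to 1")
  spec3 <- default_spec()
  spec3$twin_pairs[[1]]$rho <- 0.95  # breaks loading^2 + rho^2 < 1
  expect_error(validate_sim_spec(spec3), "loading\\^2")
})

test_that("equal specs generate byte-identical cohorts", {
  a <- generate_cohort(default_spec(n = 200, seed = 77))
  b <- generate_cohort(default_spec(n = 200, seed = 77))
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c <- generate_cohort(default_spec(n = 200, seed = 78))
  expect_false(identical(a, c))
})

test_that("with all loadings and couplings zero, items are independent", {
  spec <- default_spec(n = 1e4, seed = 31415)
  for (i in seq_along(spec$items)) spec$items[[i]]$loading <- 0
  for (k in seq_along(spec$twin_pairs)) spec$twin_pairs[[k]]$rho <- 0
  cohort <- generate_cohort(spec)
  cols <- c(paste0("zfs_", zfs_items()), paste0("msega_", msega_items()))
  cm <- stats::cor(cohort[cols])
  off <- cm[upper.tri(cm)]
  # 3 Monte-Carlo standard errors of a null correlation at n = 1e4
  expect_true(all(abs(off) < 3 / sqrt(1e4 - 3)))
})

test_that("default spec recovers every published item prevalence at n = 1e4", {
  spec <- default_spec(n = 1e4, seed = 2718)
  cohort <- generate_cohort(spec)
  targets <- table4_prevalences()$items / 102
  for (nm in names(targets)) {
    p <- targets[[nm]]
    emp <- mean(cohort[[paste0("zfs_", nm)]])
    expect_lt(abs(emp - p), 3 * sqrt(p * (1 - p) / 1e4))
  }
})

test_that("increasing a twin coupling strictly increases that pair's phi", {
  phis <- vapply(c(0, 0.25, 0.5, 0.7), function(rho) {
    spec <- default_spec(n = 1e4, seed = 555)
    spec$twin_pairs[[3]]$rho <- rho  # memory ~ cognition
    cohort <- generate_cohort(spec)
    as.numeric(pearson_r(cohort$zfs_memory, cohort$msega_cognition))
  }, numeric(1))
  expect_true(all(diff(phis) > 0))
})

test_that("item loadings rank-order the item-versus-total association", {
  spec <- default_spec(n = 2e4, seed = 90210)
  cohort <- generate_cohort(spec)
  msega_total <- rowSums(cohort[paste0("msega_", msega_items())])
  zfs_loadings <- vapply(spec$items[1:6], `[[`, numeric(1), "loading")
  item_r <- vapply(zfs_items(), function(nm) {
    as.numeric(pearson_r(cohort[[paste0("zfs_", nm)]], msega_total))
  }, numeric(1))
  # monotone association between loading and correlation (rank correlation
  # high, not exact: marginal prevalence also shapes the phi)
  expect_gt(stats::cor(zfs_loadings, item_r, method = "spearman"), 0.7)
})

test_that("calibrated defaults land near the published cross-scale summary", {
  cohort <- generate_cohort(default_spec(n = 5000, seed = 20210904))
  scores <- cohort_scores(cohort)
  expect_lt(abs(stats::cor(scores$zfs_score, scores$msega_total) - 0.81), 0.08)
  expect_lt(abs(mean(scores$msega_frail) - 0.196), 0.05)
})

test_that("demographics track the published moments and age couples to frailty", {
  cohort <- generate_cohort(default_spec(n = 1e4, seed = 1001))
  dem <- table3_demographics()
  expect_equal(mean(cohort$age), dem$moments["mean", "age"], tolerance = 0.01)
  expect_equal(mean(cohort$weight_kg), dem$moments["mean", "weight_kg"],
               tolerance = 0.01)
  expect_equal(mean(cohort$sex == "F"), 55 / 102, tolerance = 0.05)
  scores <- cohort_scores(cohort)
  expect_gt(stats::cor(cohort$age, scores$msega_total), 0.1)
  expect_gt(stats::cor(cohort$n_medications,
                       cohort$zfs_polypharmacy), 0.5)
})
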