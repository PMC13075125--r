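test_that("mean absolute error is the mean of absolute differences", {
  expect_equal(mae(c(10, 20), c(12, 17)), 2.5)
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(10, 20), c(12, 17)), mae(c(12, 17), c(10, 20)))
})

test_that("Bland-Altman statistics match hand computation", {
  ba <- bland_altman(reference = c(0, 0, 0), estimated = c(1, 2, 3))
  expect_equal(ba$bias, 2)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_low, 0.04)
  expect_equal(ba$loa_high, 3.96)
  expect_equal(ba$ci_low, 2 - 1.96 / sqrt(3))
  # internal identities
  expect_equal(ba$loa_low, ba$bias - 1.96 * ba$sd_diff, tolerance = 1e-12)
  expect_equal(ba$ci_high - ba$bias, ba$bias - ba$ci_low, tolerance = 1e-12)
  # equal differences collapse the limits onto the bias
  flat <- bland_altman(c(1, 2, 3), c(3, 4, 5))
  expect_equal(flat$loa_low, flat$bias)
  expect_equal(flat$loa_high, flat$bias)
  # direction flip negates everything
  rev <- bland_altman(c(0, 0, 0), c(1, 2, 3),
                      direction = "reference-estimated")
  expect_equal(rev$bias, -2)
  expect_error(bland_altman(c(1, 2), c(1, 2)),
               class = "gaitmark_validation_error")
})

test_that("bias CI width shrinks as 1 over sqrt(n)", {
  withr::local_seed(2)
  d <- rnorm(20, 3, 2)
  small <- bland_altman(rep(0, 20), d)
  big <- bland_altman(rep(0, 80), rep(d, 4))
  expect_equal((small$ci_high - small$ci_low) /
                 (big$ci_high - big$ci_low) * big$sd_diff / small$sd_diff,
               2, tolerance = 1e-12)
})

test_that("Spearman equals the rank-then-Pearson oracle, ties included", {
  expect_equal(spearman_rho(1:5, c(2, 4, 6, 8, 10)), 1)
  expect_equal(spearman_rho(1:5, 5:1), -1)
  withr::local_seed(13)
  for (i in 1:25) {
    x <- sample(1:4, 12, replace = TRUE) + rnorm(12, 0, 0.01)
    y <- x + sample(0:2, 12, replace = TRUE)   # plenty of ties
    oracle <- cor(rank(x, ties.method = "average"),
                  rank(y, ties.method = "average"))
    expect_equal(spearman_rho(x, y), oracle, tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 5), 1:5),
               class = "gaitmark_computation_error")
})

test_that("ICC(2,1) equals the ANOVA oracle and rewards identity", {
  expect_equal(icc21(c(1, 5, 9), c(1, 5, 9)), 1)
  fixed <- cbind(c(10, 12, 19, 25, 31, 44), c(11, 14, 18, 26, 30, 49))
  expect_equal(icc21(fixed[, 1], fixed[, 2]),
               icc_oracle(fixed[, 1], fixed[, 2]), tolerance = 1e-10)
  withr::local_seed(31)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    x <- rnorm(n, 50, 10)
    y <- x + rnorm(n, sample(c(0, 5), 1), 3)
    expect_equal(icc21(x, y), icc_oracle(x, y), tolerance = 1e-10)
  }
  expect_error(icc21(rep(3, 4), rep(3, 4)),
               class = "gaitmark_computation_error")
})

test_that("absolute agreement penalizes a constant offset; consistency does not", {
  withr::local_seed(8)
  x <- rnorm(12, 50, 8)
  y <- x + 10
  # consistency-form oracle ICC(3,1)
  n <- length(x)
  m <- cbind(x, y)
  grand <- mean(m)
  msr <- 2 * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - grand)^2)
  mse <- (sum((m - outer(rowMeans(m), c(1, 1)) -
                 outer(rep(1, n), colMeans(m)) + grand)^2)) / (n - 1)
  icc_consistency <- (msr - mse) / (msr + mse)
  expect_lt(icc21(x, y), icc_consistency)
})

test_that("coefficient bands follow the published cut points", {
  expect_equal(classify_band(0.916), "excellent")
  expect_equal(classify_band(0.798), "good")
  expect_equal(classify_band(0.499), "poor")
  expect_equal(classify_band(c(0.5, 0.75, 0.9, -0.2)),
               c("moderate", "moderate", "good", "poor"))
  expect_error(classify_band(1.2), class = "gaitmark_validation_error")
})

test_that("the normality gate selects the documented branches", {
  # heavily skewed all-positive differences: Wilcoxon, extreme statistic
  ref <- rep(0, 6)
  est <- c(0.01, 0.02, 0.03, 0.04, 0.05, 100)
  out <- paired_location_test(ref, est)
  expect_equal(out$test_used, "wilcoxon")
  expect_equal(out$p_value, 2 / 2^6)  # all signs positive, exact null
  # exactly antisymmetric normal-looking differences: t branch, p = 1
  est2 <- c(-3, -2, -1, 1, 2, 3)
  out2 <- paired_location_test(rep(0, 6), est2)
  expect_equal(out2$test_used, "paired_t")
  expect_equal(out2$p_value, 1)
  expect_error(paired_location_test(1:5, 1:5),
               class = "gaitmark_computation_error")
})

test_that("exact Wilcoxon p equals full sign-pattern enumeration", {
  withr::local_seed(17)
  for (n in c(6, 8)) {
    for (i in 1:12) {
      d <- sample(c(-1, 1), n, replace = TRUE) * seq_len(n)
      got <- paired_location_test(rep(0, n), d, branch = "wilcoxon")$p_value
      expect_equal(got, wilcoxon_enum_p(d), tolerance = 1e-12)
    }
  }
})

test_that("compare_systems reports the full battery per parameter", {
  withr::local_seed(5)
  vals <- rnorm(10, 50, 8)
  ref <- summary_table(vals)
  # identical systems: zero bias and MAE, perfect ICC, degenerate test
  same <- compare_systems(ref, ref)
  expect_equal(same$agreement$mae, 0)
  expect_equal(same$agreement$icc, 1)
  expect_equal(same$agreement$test_used, "degenerate")
  expect_true(is.na(same$agreement$p_value))
  expect_equal(same$bland_altman$bias, 0)

  # constant 3-degree offset appears as the bias of every parameter
  est <- dplyr::mutate(ref, value_deg = value_deg + 3)
  off <- compare_systems(ref, est)
  expect_equal(off$bland_altman$bias, 3)
  expect_equal(off$agreement$mae, 3)
  expect_equal(off$agreement$rho, 1)

  # subject mismatch is an alignment error listing ids
  est2 <- dplyr::mutate(est, subject = sub("S01", "S99", subject))
  expect_error(compare_systems(ref, est2), "S99",
               class = "gaitmark_validation_error")
})

test_that("report fields match independently scripted formulas", {
  cohort <- simulate_cohort(n_subjects = 12, angle_offset = 2, seed = 99)
  report <- compare_systems(cohort$reference, cohort$estimated)

  # script the same quantities directly from the session tables
  subj_mean <- function(tbl) {
    stats::aggregate(value_deg ~ subject + joint + side + parameter,
                     tbl, mean)
  }
  r <- subj_mean(cohort$reference)
  e <- subj_mean(cohort$estimated)
  key <- r$joint == "knee" & r$side == "right" & r$parameter == "flexion_max"
  rv <- r$value_deg[key][order(r$subject[key])]
  ev <- e$value_deg[key][order(e$subject[key])]

  row <- dplyr::filter(tidy(report), joint == "knee", side == "right",
                       parameter == "flexion_max")
  d <- ev - rv
  expect_equal(row$bias, mean(d), tolerance = 1e-10)
  expect_equal(row$sd_diff, sd(d), tolerance = 1e-10)
  expect_equal(row$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-10)
  expect_equal(row$mae, mean(abs(d)), tolerance = 1e-10)
  expect_equal(row$rho, cor(rank(rv), rank(ev)), tolerance = 1e-10)
  expect_equal(row$icc, icc_oracle(rv, ev), tolerance = 1e-10)
  expect_equal(row$mean_ref, mean(rv), tolerance = 1e-10)
})
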