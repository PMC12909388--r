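test_that("aggregate_levels reports mean, sample sd and n per cell", {
  rr <- function(v) as_regional_rates(v + 10, v, v - 10, v)
  recs <- rbind(
    cohort_record("A01", "high", "D5", "combined", rr(160),
                  pct_growth_modulation = 10),
    cohort_record("A02", "high", "D5", "combined", rr(160),
                  pct_growth_modulation = 20),
    cohort_record("A01", "high", "D4", "combined", rr(160),
                  pct_growth_modulation = 30))
  out <- aggregate_levels(recs, group_by = "level")
  expect_equal(out$mean[out$level == "D5"], 15)
  expect_equal(out$sd[out$level == "D5"], sd(c(10, 20)))
  expect_equal(out$sd[out$level == "D5"], 7.071, tolerance = 1e-3)
  expect_equal(out$n[out$level == "D5"], 2L)
  # single record: mean itself, sd missing
  expect_equal(out$mean[out$level == "D4"], 30)
  expect_true(is.na(out$sd[out$level == "D4"]))
  expect_error(aggregate_levels(recs, group_by = "nonexistent"), "unknown")
})

test_that("aggregating a synthetic cohort yields one row per present cell", {
  coh <- simulate_cohort(cohort_sim_params(seed = 3))
  out <- aggregate_levels(coh, group_by = c("level", "side"))
  expect_equal(nrow(out), 8L)  # 8 disk levels x 1 side
  expect_true(all(out$n == 6))
})

test_that("Grubbs' statistic and critical value match independent oracles", {
  g <- grubbs_test(c(1, 1, 1, 1, 1, 10))
  # direct formula: mean 2.5, sd sqrt(13.5), max dev 7.5
  expect_equal(g$G, 7.5 / sd(c(1, 1, 1, 1, 1, 10)))
  expect_equal(g$G, 2.041, tolerance = 1e-3)
  expect_equal(g$G_crit, 1.887, tolerance = 1e-3)  # published table, n=6
  expect_true(g$is_outlier)
  expect_equal(g$suspect, 10)

  g2 <- grubbs_test(1:6)
  expect_equal(g2$G, 1.336, tolerance = 1e-3)
  expect_false(g2$is_outlier)

  expect_error(grubbs_test(c(2, 2, 2)), "zero-variance")
  expect_error(grubbs_test(c(1, 2)), "at least 3")
})

test_that("Grubbs critical values reproduce the published two-sided table", {
  published <- c(`3` = 1.155, `4` = 1.481, `5` = 1.715, `6` = 1.887,
                 `7` = 2.020, `8` = 2.126, `9` = 2.215, `10` = 2.290)
  for (n in 3:10) {
    expect_equal(grubbs_critical(n, 0.05, "two_sided"),
                 published[[as.character(n)]], tolerance = 1e-3)
  }
  # one-sided values are smaller
  expect_lt(grubbs_critical(6, 0.05, "one_sided"),
            grubbs_critical(6, 0.05, "two_sided"))
})

test_that("G never exceeds its attainable maximum (n-1)/sqrt(n)", {
  set.seed(81)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    v <- rnorm(n) * 10^runif(1, -2, 2)
    if (sd(v) == 0) next
    expect_lte(grubbs_test(v)$G, (n - 1) / sqrt(n) + 1e-12)
  }
})

test_that("excluded values are recovered exactly from leave-one-out means", {
  expect_equal(infer_excluded_value(22.7, 6, 23.9), 16.7)
  expect_equal(infer_excluded_value(22.7, 6, 25.8), 7.2)
  expect_equal(infer_excluded_value(5, 4, 5), 5)
  # composition with re-averaging reconstructs the original mean
  set.seed(91)
  for (i in 1:20) {
    v <- rnorm(7)
    m_all <- mean(v); m_loo <- mean(v[-3])
    x <- infer_excluded_value(m_all, 7, m_loo)
    expect_equal((6 * m_loo + x) / 7, m_all, tolerance = 1e-12)
    expect_equal(x, v[3], tolerance = 1e-12)
  }
})

test_that("Bonferroni adjustment divides alpha by kappa", {
  expect_equal(bonferroni_alpha(0.05, 13), 0.05 / 13)
  expect_equal(round(bonferroni_alpha(0.05, 13), 3), 0.004)
  expect_equal(bonferroni_alpha(0.05, 7), 0.05 / 7)  # upper end: 0.0071
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 10), 0.005)
  expect_error(bonferroni_alpha(0.05, 0), "kappa")
})

test_that("pairwise one-tailed t tests behave at the null and at separation", {
  expect_equal(pairwise_one_tailed_t(list(a = c(1, 2, 3), b = c(1, 2, 3)),
                                     kappa = 1)$p_one_tailed, 0.5)
  set.seed(101)
  g <- list(a = rnorm(50, 0, 1), b = rnorm(50, 5, 1))
  out <- pairwise_one_tailed_t(g, kappa = 1)
  expect_lt(out$p_one_tailed, 1e-10)
  expect_true(out$significant)
  # kappa = 1 leaves alpha unadjusted
  expect_equal(attr(out, "adjusted_alpha"), 0.05)
  # a group with n < 2 yields an NA row, not an error
  out2 <- pairwise_one_tailed_t(list(a = 1, b = c(1, 2, 3)), kappa = 1)
  expect_true(is.na(out2$p_one_tailed))
  # three groups -> three pairs
  expect_equal(nrow(pairwise_one_tailed_t(list(a = 1:3, b = 2:5, c = 0:4),
                                          kappa = 3)), 3L)
})

test_that("required sample size matches the exact noncentral-t oracle", {
  for (d in c(0.18, 0.5, 1.0)) {
    n <- required_sample_size(d, alpha = 0.05, power = 0.80)
    oracle <- ceiling(power.t.test(delta = d, sd = 1, sig.level = 0.05,
                                   power = 0.80)$n)
    expect_equal(n, oracle)
    # minimality: power at n meets the target, at n - 1 it does not
    expect_gte(power.t.test(n = n, delta = d, sd = 1, sig.level = 0.05)$power,
               0.80)
    expect_lt(power.t.test(n = n - 1, delta = d, sd = 1, sig.level = 0.05)$power,
              0.80)
  }
  expect_equal(required_sample_size(1.0), 17L)
  expect_gte(required_sample_size(0.18),
             ceiling(2 * (qnorm(0.975) + qnorm(0.8))^2 / 0.18^2) - 2)  # ~485
  expect_error(required_sample_size(0), "d = 0")
  # degenerate boundary: target power at the test's size
  expect_equal(required_sample_size(0.5, alpha = 0.05, power = 0.04), 2L)
})

test_that("post hoc power agrees with power.t.test and is monotone in n", {
  ph <- post_hoc_power(2, 1, 0, 1, n_per_group = 6)
  expect_equal(ph$d, 2)
  expect_equal(ph$power,
               power.t.test(n = 6, delta = 2, sd = 1, sig.level = 0.05)$power,
               tolerance = 1e-6)
  # null effect: power equals the test's size (two-sided)
  expect_equal(post_hoc_power(1, 1, 1, 1, 6)$power, 0.05, tolerance = 1e-9)
  pw <- sapply(c(3, 6, 12, 24), function(n) post_hoc_power(1, 1, 0, 1, n)$power)
  expect_true(all(diff(pw) > 0))
  expect_error(post_hoc_power(1, 0, 1, 0, 6), "pooled")
})

test_that("one-way ANOVA reduces to t-squared for two groups and handles nulls", {
  set.seed(111)
  a <- rnorm(8); b <- rnorm(8, 1)
  res <- anova_oneway(list(a = a, b = b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res$p, tt$p.value, tolerance = 1e-9)

  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  res0 <- anova_oneway(same)
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)

  expect_error(anova_oneway(list(a = c(1, 1), b = c(1, 1))), "zero-variance")
  expect_error(anova_oneway(list(a = 1, b = c(1, 2))), "n >= 2")
})
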