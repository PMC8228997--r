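test_that("Mann-Whitney: exact small-sample p matches full enumeration", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)   # 2/20 of the C(6,3) assignments
  expect_equal(oracle_mw_exact(c(1, 2, 3), c(4, 5, 6)), 0.1)

  set.seed(10)
  for (i in 1:12) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- round(rnorm(n1), 4); y <- round(rnorm(n2, 0.5), 4)
    if (anyDuplicated(c(x, y))) next
    expect_equal(mann_whitney_u(x, y)$p_value, oracle_mw_exact(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney handles identical samples and rejects empty ones", {
  x <- c(1, 2, 2, 3, 5)
  r <- mann_whitney_u(x, x)
  expect_equal(r$statistic, length(x)^2 / 2)   # U = n^2/2 under exchange
  expect_equal(r$p_value, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Friedman: zero statistic on identical columns, direction agrees with the sign test", {
  m <- matrix(rep(c(3, 1, 4, 1, 5), 3), ncol = 3)
  r <- friedman_test(m)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_error(friedman_test(matrix(c(1, NA, 2, 3), 2, 2)), "incomplete")

  # k = 2: Friedman reduces to a sign test on within-pair differences
  set.seed(2)
  a <- rnorm(12); b <- a + abs(rnorm(12)) + 0.1   # b > a always
  fr <- friedman_test(cbind(a, b))
  expect_equal(unname(fr$statistic), 12)  # all 12 pairs favor b
  expect_lt(fr$p_value, 0.01)
  bt <- binom.test(12, 12)$p.value
  expect_lt(abs(fr$p_value - bt), 0.05)   # same evidence, asymptotic vs exact
})

test_that("Bonferroni post hoc multiplies p by the comparison count, clipped at 1", {
  set.seed(3)
  m <- matrix(rnorm(40), 10, 4)
  ph <- friedman_posthoc(m)
  expect_equal(nrow(ph), 6)
  expect_equal(ph$p_adjusted, pmin(1, 6 * ph$p_value))
  expect_true(all(ph$p_adjusted >= ph$p_value))
  expect_equal(unname(p.adjust(0.03, "bonferroni", n = 4)), 0.12)
})

test_that("Pearson r matches the closed-form estimate and is categorized", {
  x <- 1:10
  r1 <- pearson_corr(x, 2 * x + 1)
  expect_equal(r1$statistic, 1)
  expect_equal(r1$category, "large")

  set.seed(4)
  y <- 0.2 * x + rnorm(10, 0, 2)
  r2 <- pearson_corr(x, y)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r2$statistic, r_manual, tolerance = 1e-12)
  t_stat <- r_manual * sqrt(8 / (1 - r_manual^2))
  expect_equal(r2$p_value, 2 * pt(-abs(t_stat), 8), tolerance = 1e-12)
  cat_manual <- if (abs(r_manual) >= 0.5) "large" else
    if (abs(r_manual) >= 0.3) "medium" else
      if (abs(r_manual) >= 0.1) "small" else "negligible"
  expect_equal(r2$category, cat_manual)

  # the conventional bands: r around 0.4 reports a medium effect
  x3 <- c(0.9, 2.1, 2.8, 4.2, 4.9, 6.1, 7.2, 7.8, 9.1, 10)
  y3 <- c(-0.266, -2.325, 0.425, 2.993, 4.257, 0.836, 1.388, -0.871,
          3.011, 1.476)
  r3 <- pearson_corr(x3, y3)
  expect_true(r3$statistic >= 0.3 && r3$statistic < 0.5)
  expect_equal(r3$category, "medium")
  expect_error(pearson_corr(rep(1, 5), 1:5), "constant")
})

test_that("KS normality screen: D matches the hand formula, sane calibration", {
  x <- c(-1.2, -0.4, 0.1, 0.8, 1.9)
  r <- ks_normality(x)
  z <- sort((x - mean(x)) / sd(x))
  n <- length(z)
  d_manual <- max(pmax(seq_len(n) / n - pnorm(z),
                       pnorm(z) - (seq_len(n) - 1) / n))
  expect_equal(unname(r$statistic), d_manual, tolerance = 1e-12)
  expect_error(ks_normality(c(1, 2)), "at least 3")

  # estimated-parameter KS is conservative: normal samples rarely rejected
  set.seed(6)
  rejections <- sum(vapply(1:100, function(i)
    ks_normality(rnorm(50))$p_value <= 0.05, logical(1)))
  expect_lte(rejections, 10)
})

test_that("log-rank: null on identical groups, error without events, O-E matches risk sets", {
  t1 <- c(5, 8, 12, 20, 25); e1 <- c(1, 1, 0, 1, 0)
  r0 <- km_logrank(c(t1, t1), c(e1, e1), rep(c("a", "b"), each = 5))
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1, tolerance = 1e-12)
  expect_error(km_logrank(c(1, 2, 3, 4), c(0, 0, 0, 0),
                          c("a", "a", "b", "b")), "no events")
  expect_error(km_logrank(1:4, c(1, 0, 1, 0), rep("a", 4)), "two groups")

  # classic two-group toy data: observed/expected from explicit risk sets
  times <- c(6, 6, 6, 7, 10, 13, 16, 22, 23, 6, 9, 10, 11, 17, 19, 20, 25, 32)
  events <- c(1, 1, 1, 1, 0, 1, 1, 1, 1, 1, 1, 1, 1, 0, 1, 1, 1, 1)
  groups <- rep(c("treated", "control"), c(9, 9))
  r <- km_logrank(times, events, groups)
  oe <- oracle_logrank_oe(times, events, groups)
  expect_equal(unname(r$extra$observed), unname(oe$observed[c("control", "treated")]),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(unname(r$extra$expected), unname(oe$expected[c("control", "treated")]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("stat_result enforces probability bounds", {
  expect_error(stat_result("t", 1, 1.2), "p_value")
  expect_error(stat_result("t", 1, 0.5, p_adjusted = 0.2))
  r <- stat_result("t", 1, 0.04, p_adjusted = 0.2)
  expect_s3_class(r, "stat_result")
})

test_that("per-timepoint group comparisons cover every day and pair", {
  co <- generate_cohort(cohort_design(n_per_group = 5, seed = 8))
  tab <- compare_groups(co, "lymphatic_density_pct")
  expect_equal(nrow(tab), 5 * 3)   # 5 days x 3 group pairs
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
})
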