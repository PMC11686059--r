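test_that("Friedman statistic agrees with base R and is rank-invariant", {
  set.seed(1)
  y <- matrix(rnorm(10 * 4), 10, 4)
  mine <- friedman_test(y)
  base <- stats::friedman.test(y)
  expect_equal(mine$statistic, unname(base$statistic))
  expect_equal(mine$p.value, base$p.value)
  # monotone within-subject transformation leaves the statistic unchanged
  expect_equal(friedman_test(exp(y))$statistic, mine$statistic)
  y2 <- y; y2[3, 2] <- NA
  expect_error(friedman_test(y2), "missing")
})

test_that("exact Friedman p equals the closed-form enumeration value", {
  # strictly ordered within every subject: the statistic is maximal and
  # exactly 3! of the (3!)^6 equally likely rank assignments attain it
  set.seed(2)
  y <- matrix(rep(c(1, 2, 3), each = 6), 6, 3) + matrix(rnorm(18, 0, 1e-3), 6, 3)
  fe <- friedman_test(y, exact = TRUE)
  expect_equal(fe$p.value, factorial(3) / factorial(3)^6, tolerance = 1e-12)
  # exact and asymptotic agree roughly on unordered data
  y3 <- matrix(rnorm(5 * 3), 5, 3)
  pe <- friedman_test(y3, exact = TRUE)$p.value
  pa <- friedman_test(y3)$p.value
  expect_lt(abs(pe - pa), 0.15)
  expect_error(friedman_test(matrix(rnorm(40 * 5), 40, 5), exact = TRUE),
               "enumeration")
})

test_that("subject-wise permutations of a common set give a null Friedman result", {
  set.seed(3)
  vals <- rnorm(7)
  y <- t(replicate(12, sample(vals)))
  expect_gt(friedman_test(y)$p.value, 0.2)
})

test_that("signed-rank exact p matches full sign enumeration at n = 8", {
  set.seed(4)
  for (s in 1:5) {
    d <- round(rnorm(8, 0.4, 1), 3)
    while (any(d == 0) || anyDuplicated(abs(d)) > 0)
      d <- round(rnorm(8, 0.4, 1), 3)
    res <- signed_rank_test(d)
    expect_equal(res$p.value, oracle_signed_rank_p(d), tolerance = 1e-12)
  }
})

test_that("Pratt variant retains zeros in the ranking", {
  d <- c(0, 0, 1.5, -2, 3, -0.5, 2.5, 4, -1, 0)
  pw <- signed_rank_test(d, zero_method = "pratt")
  # independently verified against scipy.stats.wilcoxon(zero_method="pratt")
  expect_equal(pw$p.value, 0.4061552, tolerance = 1e-6)
  expect_equal(pw$n_effective, 7L)
  ww <- signed_rank_test(d, zero_method = "wilcox")
  expect_equal(ww$p.value, 0.296875, tolerance = 1e-12)
})

test_that("degenerate all-zero differences flag p = 1", {
  res <- signed_rank_test(rep(0, 10))
  expect_true(res$degenerate)
  expect_equal(res$p.value, 1)
})

test_that("pairwise table covers all pairs with monotone correction", {
  set.seed(5)
  y <- matrix(rnorm(10 * 7), 10, 7,
              dimnames = list(NULL, ne_conditions()))
  y[, "rest"] <- y[, "rest"] - 1.5          # one strong contrast
  tab <- pairwise_wilcoxon(y)
  expect_equal(nrow(tab), choose(7, 2))
  expect_true(all(tab$p_adjusted >= tab$p_raw - 1e-15))
  # Holm preserves the raw-p ordering
  ord <- order(tab$p_raw)
  expect_true(all(diff(tab$p_adjusted[ord]) >= -1e-15))
  # identical columns give a flagged p = 1 row
  y2 <- cbind(a = y[, 1], b = y[, 1], c = y[, 2])
  tab2 <- pairwise_wilcoxon(y2)
  ab <- tab2[tab2$condition_a == "a" & tab2$condition_b == "b", ]
  expect_true(ab$degenerate)
  expect_equal(ab$p_raw, 1)
  tab3 <- pairwise_wilcoxon(y, method = "BH")
  expect_true(all(tab3$p_adjusted >= tab3$p_raw - 1e-15))
})

test_that("actual-vs-null comparison reports direction and antisymmetry", {
  set.seed(6)
  a <- rnorm(20, -0.3, 0.05); b <- a + abs(rnorm(20, 0.2, 0.05))
  r1 <- actual_vs_null_test(a, b)
  r2 <- actual_vs_null_test(b, a)
  expect_equal(r1$direction, "actual < null")
  expect_equal(r2$direction, "actual > null")
  expect_equal(r1$p.value, r2$p.value)
  same <- actual_vs_null_test(a, a)
  expect_true(same$degenerate)
  expect_equal(same$p.value, 1)
  expect_error(actual_vs_null_test(a, b[-1]), "equal length")
})

test_that("ICC(3,k) matches the two-way ANOVA variance components", {
  set.seed(7)
  n <- 24
  subj_eff <- rnorm(n, 0, 6)
  a <- 30 + subj_eff + rnorm(n, 0, 2)
  b <- 28 + subj_eff + rnorm(n, 0, 2)
  res <- icc_consistency(a, b)
  # independent route: mean squares from stats::aov on the long layout
  long <- data.frame(score = c(a, b),
                     subj = factor(rep(seq_len(n), 2)),
                     rater = factor(rep(c("a", "b"), each = n)))
  ms <- summary(stats::aov(score ~ subj + rater, data = long))[[1]]
  msr <- ms["subj", "Mean Sq"]; mse <- ms["Residuals", "Mean Sq"]
  expect_equal(res$icc, (msr - mse) / msr, tolerance = 1e-10)
  expect_true(res$ci_low <= res$icc && res$icc <= res$ci_high)
  # perfect agreement and additive shifts give ICC 1; multiplicative
  # rescaling does not (consistency removes rater means, not scales):
  # with b = 2a + 3 the population value is 8/9, checked via pingouin
  expect_equal(icc_consistency(a, a)$icc, 1)
  expect_equal(icc_consistency(a, a + 3)$icc, 1)
  expect_equal(icc_consistency(a, 2 * a + 3)$icc, 8 / 9, tolerance = 1e-12)
  expect_error(icc_consistency(rep(1, 10), rep(2, 10)), "between-subject")
  expect_error(icc_consistency(a[1:3], b[1:3]), "5 subjects")
})
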