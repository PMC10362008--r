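test_that("pairwise Pearson correlation handles identity, constructed
          orthogonality and missingness; errors on degenerate input", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_pairwise(a, a)$r, 1)
  # orthogonalized b: residual of another vector on a (with intercept)
  b <- residuals(lm(c(2, 1, 4, 3, 6) ~ a))
  expect_lt(abs(pearson_pairwise(a, b)$r), 1e-12)
  # joint observation counting
  aa <- c(a, NA, 7); bb <- c(a, 3, NA)
  expect_equal(pearson_pairwise(aa, bb)$n_effective, 5)
  expect_error(pearson_pairwise(c(1, 2, NA), c(1, NA, 2)), "fewer than 3")
  expect_error(pearson_pairwise(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("sample correlations concentrate on the population value
          (bivariate normal, rho = 0.3)", {
  set.seed(31)
  reps <- 5000; n <- 200; rho <- 0.3
  rs <- numeric(reps)
  for (r in seq_len(reps)) {
    z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    rs[r] <- pearson_pairwise(z1, z2)$r
  }
  # allow the O((1 - rho^2) rho / (2n)) small-sample bias
  bias <- -(1 - rho^2) * rho / (2 * n)
  expect_lt(abs(mean(rs) - (rho + bias)), 3 * sd(rs) / sqrt(reps))
})

test_that("the overlapping dependent-correlation test is zero on the nose
          under equality, antisymmetric in (j, k), and matches the
          independent formula oracle", {
  # exact null: statistic 0, p = 1
  for (m in c("steiger", "williams")) {
    res <- dependent_overlapping_test(0.4, 0.4, 0.2, 100, method = m)
    expect_equal(res$statistic, 0)
    expect_equal(res$p, 1)
  }
  # antisymmetry
  for (m in c("steiger", "williams")) {
    r1 <- dependent_overlapping_test(0.5, 0.3, 0.2, 100, method = m)
    r2 <- dependent_overlapping_test(0.3, 0.5, 0.2, 100, method = m)
    expect_equal(r1$statistic, -r2$statistic)
    expect_equal(r1$p, r2$p)
  }
  # independent implementation of the published Steiger formula
  z_oracle <- oracle_steiger_z(0.5, 0.3, 0.2, 100)
  res <- dependent_overlapping_test(0.5, 0.3, 0.2, 100)
  expect_equal(res$statistic, z_oracle, tolerance = 1e-12)
  expect_equal(res$p, 2 * pnorm(-abs(z_oracle)), tolerance = 1e-12)

  # degenerate and inconsistent inputs
  expect_error(dependent_overlapping_test(1, 0.3, 0.2, 50), "degenerate")
  expect_error(dependent_overlapping_test(0.9, -0.9, 0.9, 50),
               "positive semidefinite")
})

test_that("the Steiger p-value agrees with the simulated null distribution
          of the statistic at matched population values", {
  # under H0 rho_jy = rho_ky = 0.4, rho_jk = 0.2, the statistic should be
  # approximately standard normal: compare the observed-p of a fixed
  # statistic against the simulated tail mass
  set.seed(32)
  reps <- 20000; n <- 100
  zs <- numeric(reps)
  for (r in seq_len(reps)) {
    m <- rtrivariate(n, r_jk = 0.2, r_jy = 0.4, r_ky = 0.4)
    zs[r] <- dependent_overlapping_test(cor(m[, 1], m[, 3]),
                                        cor(m[, 2], m[, 3]),
                                        cor(m[, 1], m[, 2]), n)$statistic
  }
  for (zq in c(1, 1.5, 2)) {
    emp_tail <- mean(abs(zs) > zq)
    nominal <- 2 * pnorm(-zq)
    se <- sqrt(nominal * (1 - nominal) / reps)
    expect_lt(abs(emp_tail - nominal), 4 * se)
  }
})

test_that("Zou's interval method brackets the difference and flags only
          intervals excluding zero", {
  res <- dependent_overlapping_test(0.6, 0.2, 0.3, 200, method = "zou")
  expect_lt(res$ci_lower, 0.6 - 0.2)
  expect_gt(res$ci_upper, 0.6 - 0.2)
  expect_true(res$significant)
  res2 <- dependent_overlapping_test(0.32, 0.3, 0.5, 100, method = "zou")
  expect_false(res2$significant)
})

test_that("Bonferroni adjustment multiplies by the family size, caps at 1,
          and is monotone", {
  expect_equal(bonferroni_adjust(0.01, 4), 0.04)
  expect_equal(bonferroni_adjust(0.6, 2), 1)
  expect_equal(bonferroni_adjust(0.123, 1), 0.123)
  ps <- seq(0, 1, by = 0.05)
  expect_true(all(diff(bonferroni_adjust(ps, 3)) >= 0))
  expect_true(all(bonferroni_adjust(ps, 7) <= 1))
  expect_equal(default_family_sizes(),
               c(impulsive_behavior = 2L, substance_use = 4L))
})

test_that("outcome tables validate family labels and id alignment", {
  vals <- cbind(urgency = rnorm(5), tobacco = rnorm(5))
  fams <- c(urgency = "impulsive_behavior", tobacco = "substance_use")
  ot <- outcome_table(vals, paste0("p", 1:5), fams)
  expect_s3_class(ot, "outcome_table")
  expect_error(outcome_table(vals, paste0("p", 1:5),
                             c(urgency = "impulsive_behavior")),
               "tobacco")
  expect_error(outcome_table(vals, paste0("p", 1:5),
                             c(urgency = "bad_family",
                               tobacco = "substance_use")),
               "family")
})

test_that("comparison tables: identical feature values give zero statistics;
          all-missing outcomes are excluded with a warning; participant
          order does not matter", {
  set.seed(33)
  n <- 60
  v <- cbind(rnorm(n), rnorm(n))
  v_dup <- cbind(v[, 1], v[, 1])
  y <- rnorm(n)
  ot <- outcome_table(cbind(out = y), paste0("p", 1:n),
                      c(out = "impulsive_behavior"))
  tab <- build_comparison_table(v_dup, ot)
  expect_equal(tab$comparisons$statistic, 0)
  expect_equal(tab$comparisons$p, 1)

  ot2 <- outcome_table(cbind(out = y, gone = rep(NA_real_, n)),
                       paste0("p", 1:n),
                       c(out = "impulsive_behavior",
                         gone = "substance_use"))
  expect_warning(tab2 <- build_comparison_table(v, ot2), "excluded")
  expect_equal(tab2$excluded_outcomes, "gone")

  # permutation invariance
  tab_v <- build_comparison_table(v, ot)
  perm <- sample(n)
  ot3 <- outcome_table(cbind(out = y[perm]), paste0("p", 1:n),
                       c(out = "impulsive_behavior"))
  tab3 <- build_comparison_table(v[perm, ], ot3)
  expect_equal(tab3$comparisons$statistic, tab_v$comparisons$statistic,
               tolerance = 1e-12)
  expect_equal(tab3$correlations$r, tab_v$correlations$r,
               tolerance = 1e-12)
})

test_that("comparisons use the jointly observed subsample so the correlation
          triple is internally consistent", {
  set.seed(34)
  n <- 80
  v <- cbind(rnorm(n), rnorm(n))
  y <- rnorm(n)
  v[1:10, 1] <- NA; y[71:80] <- NA
  ot <- outcome_table(cbind(out = y), paste0("p", 1:n),
                      c(out = "substance_use"))
  tab <- build_comparison_table(v, ot)
  cmp <- tab$comparisons
  ok <- !is.na(v[, 1]) & !is.na(v[, 2]) & !is.na(y)
  expect_equal(cmp$n, sum(ok))
  expect_equal(cmp$r_jk, cor(v[ok, 1], v[ok, 2]))
  expect_equal(cmp$bonferroni_m, 4)
})
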