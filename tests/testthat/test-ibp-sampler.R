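test_that("conditional inclusion probability reduces to the prior m/N for a
          fully masked row and follows the likelihood otherwise", {
  hyp <- ibp_hyperparameters(alpha = 1, sigma_x = 1, sigma_a = 1)
  z <- matrix(c(1, 1, 1, 0, 0, 0,
                0, 1, 0, 1, 1, 0), 6, 2)
  a <- matrix(c(2, 0, 0, 2), 2, 2)
  st <- ibp_state(z, a, hyp)
  # row 6 fully masked: probability is exactly m / N
  x <- matrix(rnorm(12), 6, 2)
  x[6, ] <- NA
  expect_equal(conditional_inclusion_probability(st, x, 6, 1), 3 / 6)
  expect_equal(conditional_inclusion_probability(st, x, 6, 2), 3 / 6)

  # likelihood-dominated limit: data exactly at the feature's signature
  x2 <- matrix(0, 6, 2)
  x2[1, ] <- c(2, 0) * 20  # strongly aligned with feature 1 at small noise
  st2 <- ibp_state(z, a * 20, ibp_hyperparameters(sigma_x = 0.1))
  expect_gt(conditional_inclusion_probability(st2, x2, 1, 1), 1 - 1e-10)

  # empty-excluding-row column is the new-feature step's business
  z3 <- z; z3[, 2] <- 0; z3[2, 2] <- 1
  st3 <- ibp_state(z3, a, hyp)
  expect_error(conditional_inclusion_probability(st3, x, 2, 2),
               "new-feature")
})

test_that("propose_new_features adds nothing when alpha = 0 or the cap is
          exhausted", {
  hyp0 <- ibp_hyperparameters(sigma_x = 1, sigma_a = 1)
  hyp0$alpha <- 0
  x <- matrix(rnorm(8), 4, 2)
  st <- ibp_state(matrix(0, 4, 0), matrix(0, 0, 2), hyp0)
  st$alpha <- 0
  set.seed(1)
  expect_equal(ncol(propose_new_features(st, x, 1)$z), 0)

  st2 <- ibp_state(matrix(0, 4, 0), matrix(0, 0, 2),
                   ibp_hyperparameters(alpha = 5))
  expect_equal(ncol(propose_new_features(st2, x, 1, k_cap = 0)$z), 0)
})

test_that("resample_noise_scales: zero proposal scale leaves both scales
          unchanged; sigma_x recovers the planted noise with A at truth", {
  set.seed(8)
  z <- matrix(rbinom(40, 1, 0.4), 20, 2)
  a <- matrix(rnorm(4), 2, 2)
  x <- z %*% a + matrix(rnorm(40, 0, 0.5), 20, 2)
  hyp <- ibp_hyperparameters(sigma_proposal_scale = 0)
  st <- ibp_state(z, a, hyp)
  expect_equal(resample_noise_scales(st, x),
               c(sigma_x = 1, sigma_a = 1))

  # recovery: large N x D, A fixed at truth, chain mean within 5%
  set.seed(9)
  n <- 200; d <- 27
  z2 <- matrix(rbinom(n * 3, 1, 0.3), n, 3)
  a2 <- matrix(rnorm(3 * d), 3, d)
  x2 <- z2 %*% a2 + matrix(rnorm(n * d, 0, 0.5), n, d)
  st2 <- ibp_state(z2, a2, ibp_hyperparameters(sigma_x = 1, sigma_a = 1))
  chain <- numeric(300)
  for (it in seq_len(300)) {
    sc <- resample_noise_scales(st2, x2)
    st2$sigma_x <- sc[["sigma_x"]]
    chain[it] <- sc[["sigma_x"]]
  }
  expect_lt(abs(mean(chain[-(1:50)]) - 0.5) / 0.5, 0.05)
})

test_that("identical seeds and settings give bit-identical traces
          (determinism) for both row-update methods", {
  set.seed(10)
  x <- matrix(rnorm(60), 20, 3)
  for (m in c("accelerated", "explicit")) {
    f1 <- run_ibp(x, sweeps = 8, seed = 42, method = m)
    f2 <- run_ibp(x, sweeps = 8, seed = 42, method = m)
    expect_identical(f1$trace, f2$trace)
    expect_identical(f1$state$z, f2$state$z)
  }
})

test_that("the first trace record carries the initialized hyperparameters
          (alpha = 5) and trace K matches the retained column count", {
  set.seed(11)
  x <- matrix(rnorm(40), 20, 2)
  fit <- run_ibp(x, sweeps = 5, seed = 3)
  expect_equal(fit$trace$alpha[1], 5)
  expect_equal(fit$trace$iteration, 0:5)
  expect_equal(fit$trace$k[6], ncol(fit$state$z))
})

test_that("no retained all-zero columns after any sweep, for both methods
          and random masked data (pruning safety)", {
  set.seed(12)
  for (m in c("accelerated", "explicit")) {
    x <- matrix(rnorm(80), 20, 4)
    x[runif(80) < 0.15] <- NA
    fit <- run_ibp(x, sweeps = 15, seed = 7, method = m)
    st <- fit$state
    for (s in 1:5) {
      st <- gibbs_sweep(st, x, method = m)
      if (ncol(st$z) > 0) expect_true(all(colSums(st$z) >= 1))
      expect_equal(st$last_record[["k"]], ncol(st$z))
    }
  }
})

test_that("a zero-column state on pure noise with alpha = 0 stays
          zero-column", {
  hyp <- ibp_hyperparameters()
  st <- ibp_state(matrix(0, 6, 0), matrix(0, 0, 2), hyp)
  st$alpha <- 0
  x <- matrix(rnorm(12), 6, 2)
  set.seed(13)
  for (m in c("accelerated", "explicit")) {
    out <- gibbs_sweep(st, x, update_alpha = FALSE, method = m)
    expect_equal(ncol(out$z), 0)
  }
})

test_that("sweep count below 1 is a configuration error", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(run_ibp(x, sweeps = 0), "sweeps")
})

test_that("continuous feature values are probabilities, equal m/N on a fully
          masked row, and approach 1 for strongly supported members", {
  set.seed(14)
  cfg <- synthetic_config(n_participants = 60, n_measures = 8, planted_k = 2,
                          noise_sd = 0.2, missing_rate = 0,
                          membership_probs = 0.4, raw_shift = FALSE,
                          seed = 14)
  ds <- generate_dataset(cfg)
  x <- ds$battery$values
  x[1, ] <- NA  # fully masked row
  fit <- run_ibp(x, sweeps = 30, seed = 5)
  vals <- continuous_feature_values(fit$state, x)
  expect_true(all(vals$values >= 0 & vals$values <= 1))
  n <- nrow(x)
  cs <- colSums(fit$state$z)
  expect_equal(vals$values[1, ],
               (cs - fit$state$z[1, ]) / n)
  # strongly supported member: a row with z = 1 on a popular feature and
  # clean signal should have value near 1
  pop <- which.max(cs)
  members <- which(fit$state$z[, pop] == 1 & seq_len(n) != 1)
  expect_gt(max(vals$values[members, pop]), 0.99)
})

test_that("the two row-update methods agree with the enumeration posterior
          over K on a small complete-data instance", {
  # small but nontrivial: N = 3, D = 2, K <= 2, fixed hyperparameters
  x <- matrix(c(1.1, -0.7, 0.4, -0.9, 1.3, -0.2), 3, 2)
  target <- enumerate_posterior_k(x, alpha = 1, sigma_x = 0.6, sigma_a = 1,
                                  max_k = 2)
  hyp <- ibp_hyperparameters(alpha = 1, sigma_x = 0.6, sigma_a = 1)
  for (m in c("accelerated", "explicit")) {
    fit <- run_ibp(x, sweeps = 12000, seed = 17, hypers = hyp, k_cap = 2,
                   max_k = 2, update_alpha = FALSE, update_scales = FALSE,
                   method = m)
    kt <- fit$trace$k[-seq_len(1001)]
    emp <- tabulate(kt + 1, 3) / length(kt)
    tv <- 0.5 * sum(abs(emp - target))
    expect_lt(tv, 0.05)
  }
})

test_that("window-averaged feature values track final-state memberships on
          clean data", {
  set.seed(15)
  cfg <- synthetic_config(n_participants = 80, n_measures = 10, planted_k = 2,
                          noise_sd = 0.2, missing_rate = 0,
                          membership_probs = 0.4, raw_shift = FALSE,
                          seed = 15)
  ds <- generate_dataset(cfg)
  fit <- run_ibp(ds$battery$values, sweeps = 30, seed = 6,
                 value_window = 10)
  expect_false(is.null(fit$window_values))
  expect_equal(dim(fit$window_values), dim(fit$state$z))
  expect_true(all(fit$window_values >= 0 & fit$window_values <= 1))
  # members at the final state should have high window occupancy
  occ <- fit$window_values[fit$state$z == 1]
  expect_gt(mean(occ), 0.8)
})
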