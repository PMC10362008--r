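test_that("planted models honour membership probabilities and the block
          weight structure", {
  # degenerate membership probability is rejected at config time
  expect_error(synthetic_config(membership_probs = 0), "strictly in")

  cfg2 <- synthetic_config(n_participants = 400, planted_k = 5,
                           membership_probs = 0.2, seed = 42)
  pm <- plant_model(cfg2)
  expect_equal(dim(pm$z_true), c(400, 5))
  # disjoint nonzero support under block weights
  support <- apply(pm$a_true != 0, 1, which)
  expect_equal(length(Reduce(intersect, support)), 0)
  all_measures <- sort(unique(unlist(support)))
  expect_equal(all_measures, 1:27)

  # binomial expectation of column popularity over seeded draws
  pops <- vapply(1:300, function(s) {
    colSums(plant_model(synthetic_config(n_participants = 100,
                                         planted_k = 2,
                                         membership_probs = 0.3,
                                         seed = s))$z_true)[1]
  }, numeric(1))
  se <- sqrt(100 * 0.3 * 0.7) / sqrt(300)
  expect_lt(abs(mean(pops) - 30), 3 * se)

  expect_error(synthetic_config(planted_k = 30, n_measures = 27),
               "planted_k <= n_measures")
})

test_that("generated batteries are the planted linear-Gaussian model plus
          noise with the requested missing rate", {
  cfg <- synthetic_config(n_participants = 100, n_measures = 27,
                          planted_k = 3, noise_sd = 0, missing_rate = 0,
                          raw_shift = FALSE, seed = 43)
  pm <- plant_model(cfg)
  b <- generate_battery(pm, cfg)
  expect_equal(b$values, pm$z_true %*% pm$a_true, ignore_attr = TRUE)

  # missing count near its binomial expectation
  cfg2 <- synthetic_config(n_participants = 1000, n_measures = 27,
                           planted_k = 3, missing_rate = 0.1,
                           raw_shift = FALSE, seed = 44)
  b2 <- generate_battery(plant_model(cfg2), cfg2)
  n_missing <- sum(!b2$mask)
  expect_lt(abs(n_missing - 2700), 3 * sqrt(27000 * 0.1 * 0.9))

  # residual SD close to noise_sd at large N x D
  cfg3 <- synthetic_config(n_participants = 500, n_measures = 27,
                           planted_k = 3, noise_sd = 0.5, missing_rate = 0,
                           raw_shift = FALSE, seed = 45)
  pm3 <- plant_model(cfg3)
  b3 <- generate_battery(pm3, cfg3)
  resid <- b3$values - pm3$z_true %*% pm3$a_true
  expect_lt(abs(sd(resid) - 0.5) / 0.5, 0.05)
})

test_that("raw-shifted batteries standardize back to clean z-scores through
          the preprocessing pipeline", {
  cfg <- synthetic_config(n_participants = 150, planted_k = 4,
                          missing_rate = 0.05, raw_shift = TRUE, seed = 46)
  ds <- generate_dataset(cfg)
  std <- suppressMessages(preprocess_battery(ds$battery))
  for (j in seq_len(ncol(std$values))) {
    obs <- std$values[std$mask[, j], j]
    expect_lt(abs(mean(obs)), 1e-9)
    expect_lt(abs(sd(obs) - 1), 1e-9)
  }
})

test_that("generated outcomes achieve their target correlations with planted
          memberships and reject infeasible specs", {
  cfg <- synthetic_config(
    n_participants = 5000, planted_k = 1, membership_probs = 0.3,
    outcome_specs = list(list(name = "y", family = "impulsive_behavior",
                              rho = 0.3)),
    seed = 47)
  ds <- generate_dataset(cfg)
  r <- pearson_pairwise(ds$outcomes$values[, "y"],
                        ds$planted$z_true[, 1])$r
  expect_lt(abs(r - 0.3), 3 / sqrt(5000))

  # null construction: rho = 0 gives small sample correlation
  cfg0 <- synthetic_config(
    n_participants = 2000, planted_k = 1, membership_probs = 0.3,
    outcome_specs = list(list(name = "y", family = "substance_use",
                              rho = 0)),
    seed = 48)
  ds0 <- generate_dataset(cfg0)
  r0 <- pearson_pairwise(ds0$outcomes$values[, "y"],
                         ds0$planted$z_true[, 1])$r
  expect_lt(abs(r0), 3 / sqrt(2000))

  expect_error(generate_outcomes(plant_model(synthetic_config(
    planted_k = 2, membership_probs = 0.2,
    outcome_specs = list(list(name = "y", family = "substance_use",
                              rho = c(0.8, 0.7)))))),
    "infeasible")
})

test_that("mean sample correlation across seeded datasets is within 0.02 of
          the target", {
  rs <- vapply(1:150, function(s) {
    cfg <- synthetic_config(
      n_participants = 2000, planted_k = 1, membership_probs = 0.3,
      outcome_specs = list(list(name = "y", family = "impulsive_behavior",
                                rho = 0.25)),
      seed = s)
    ds <- generate_dataset(cfg)
    pearson_pairwise(ds$outcomes$values[, "y"], ds$planted$z_true[, 1])$r
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.25), 0.02)
})

test_that("demographics stay inside the 18-55 inclusion band with the
          requested composition, deterministically", {
  d1 <- generate_demographics(800, seed = 49)
  expect_true(all(d1$age >= 18 & d1$age <= 55))
  p_female <- mean(d1$sex == "female")
  expect_lt(abs(p_female - 0.64), 3 * sqrt(0.64 * 0.36 / 800))
  d2 <- generate_demographics(800, seed = 49)
  expect_identical(d1, d2)
})

test_that("datasets are deterministic in (config, seed) and share ids across
          components", {
  cfg <- synthetic_config(n_participants = 40, planted_k = 2, seed = 50)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$battery$values, d2$battery$values)
  expect_identical(d1$outcomes$values, d2$outcomes$values)
  expect_identical(d1$demographics, d2$demographics)
  expect_identical(d1$battery$participant_ids,
                   d1$outcomes$participant_ids)
  expect_identical(d1$battery$participant_ids,
                   d1$demographics$participant_id)
})

test_that("recovery reports are pure functions of their inputs and hit the
          perfect-information limit on clean data", {
  cfg <- synthetic_config(n_participants = 120, n_measures = 12,
                          planted_k = 3, noise_sd = 0.05, missing_rate = 0,
                          membership_probs = 0.4, raw_shift = FALSE,
                          seed = 51)
  ds <- generate_dataset(cfg)
  fit <- run_ibp(ds$battery, sweeps = 30, seed = 8)
  r1 <- recovery_report(ds, fit)
  r2 <- recovery_report(ds, fit)
  expect_identical(r1$matches, r2$matches)
  expect_equal(r1$modal_k, 3)
  expect_true(all(r1$matches$auc == 1))
})

test_that("write_dataset emits CSVs and a ground-truth JSON that round-trip", {
  cfg <- synthetic_config(n_participants = 12, n_measures = 5, planted_k = 2,
                          seed = 52)
  ds <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth$z_true, ds$planted$z_true, ignore_attr = TRUE)
  batt <- utils::read.csv(paths["battery"])
  expect_equal(nrow(batt), 12)
})
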