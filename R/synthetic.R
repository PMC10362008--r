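#' Configuration for the synthetic data generator
#'
#' Defines a planted linear-Gaussian latent feature model and the outcome /
#' demographic structure emulating a multi-task neurocognitive study. The
#' defaults mirror the study conditions the package targets: 673
#' participants, 27 measures, 5 planted features (the number of retained,
#' interpretable features), block weights so each feature loads on a
#' disjoint set of measures, and moderate noise and missingness.
#'
#' @param n_participants Number of participants. Default 673.
#' @param n_measures Number of battery measures. Default 27.
#' @param planted_k Number of planted features. Default 5.
#' @param weight_scale SD of nonzero planted weights. Default 1.
#' @param noise_sd Observation noise SD. Default 0.5.
#' @param missing_rate Per-cell missing-completely-at-random probability in
#'   \[0, 1). Default 0.05.
#' @param membership_probs Per-feature Bernoulli membership probabilities in
#'   (0, 1); recycled to `planted_k`. Default 0.2. Independent Bernoulli
#'   memberships (not the IBP prior) keep feature popularity — and hence
#'   filter behavior — controllable.
#' @param block_weights If `TRUE` (default) each feature loads on a disjoint
#'   block of measures (interpretable recovery); otherwise weights are dense
#'   `N(0, weight_scale^2)`.
#' @param outcome_specs A list of outcome specifications, each a list with
#'   `name`, `family` (`"impulsive_behavior"` or `"substance_use"`), and
#'   `rho` (length-`planted_k` vector of target population correlations
#'   between the outcome and each planted membership indicator). Default:
#'   one impulsive-behavior outcome correlated 0.3 with feature 1.
#' @param sex_probs,race_probs Named probability vectors for the demographic
#'   draws. Defaults reflect the study sample (64% female; 67% White, 21%
#'   Black, 6% Asian, 6% other).
#' @param raw_shift If `TRUE` (default), the emitted battery is shifted and
#'   scaled per measure so the preprocessing stage is exercised end-to-end;
#'   if `FALSE` the battery stays on the model's natural scale (used for
#'   parameter recovery, where the planted `noise_sd` must remain
#'   comparable).
#' @param seed Integer seed. Default 1.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_participants = 673, n_measures = 27,
                             planted_k = 5, weight_scale = 1,
                             noise_sd = 0.5, missing_rate = 0.05,
                             membership_probs = 0.2, block_weights = TRUE,
                             outcome_specs = list(
                               list(name = "outcome_1",
                                    family = "impulsive_behavior",
                                    rho = c(0.3, rep(0, planted_k - 1)))),
                             sex_probs = c(female = 0.64, male = 0.36),
                             race_probs = c(white = 0.67, black = 0.21,
                                            asian = 0.06, other = 0.06),
                             raw_shift = TRUE, seed = 1L) {
  stopifnot(n_participants >= 1, n_measures >= 1, planted_k >= 0,
            weight_scale > 0, noise_sd >= 0,
            missing_rate >= 0, missing_rate < 1)
  membership_probs <- rep_len(membership_probs, planted_k)
  if (planted_k > 0 &&
      any(membership_probs <= 0 | membership_probs >= 1)) {
    stop("membership_probs must lie strictly in (0, 1)", call. = FALSE)
  }
  if (block_weights && planted_k > 0 && planted_k > n_measures) {
    stop("block weights require planted_k <= n_measures", call. = FALSE)
  }
  for (os in outcome_specs) {
    stopifnot(is.character(os$name),
              os$family %in% c("impulsive_behavior", "substance_use"))
    if (length(os$rho) != planted_k) {
      stop("outcome spec '", os$name, "' needs one rho per planted feature",
           call. = FALSE)
    }
    if (any(abs(os$rho) >= 1)) {
      stop("outcome spec '", os$name, "': |rho| must be < 1", call. = FALSE)
    }
  }
  structure(list(n_participants = n_participants, n_measures = n_measures,
                 planted_k = planted_k, weight_scale = weight_scale,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 membership_probs = membership_probs,
                 block_weights = block_weights,
                 outcome_specs = outcome_specs, sex_probs = sex_probs,
                 race_probs = race_probs, raw_shift = raw_shift,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# schema for a synthetic battery of arbitrary width: reuse the bundled
# 27-measure schema when the width matches, otherwise generic CNB-style rows
synthetic_schema <- function(d) {
  if (d == 27) return(default_schema())
  measure_schema(data.frame(
    measure_id = sprintf("measure_%02d", seq_len(d)), battery = "CNB",
    subfunction = "synthetic", score_label = "Synthetic score",
    higher_is_better_raw = TRUE, reverse_score = FALSE,
    stringsAsFactors = FALSE))
}

#' Draw a planted ground-truth model
#'
#' Memberships `z_true` are independent Bernoulli draws per feature (not the
#' IBP prior, so popularity — and the filter threshold — is controllable).
#' Weights `a_true` are `N(0, weight_scale^2)`; with `block_weights` each
#' feature's nonzero support is a disjoint block of measures.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `planted_model`: `z_true` (N x K binary),
#'   `a_true` (K x D), `noise_sd`, `membership_probs`, `config`.
#' @export
plant_model <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_participants; d <- config$n_measures; k <- config$planted_k
  z_true <- matrix(0L, n, k)
  for (j in seq_len(k)) {
    z_true[, j] <- stats::rbinom(n, 1, config$membership_probs[j])
  }
  a_true <- matrix(0, k, d)
  if (k > 0) {
    if (config$block_weights) {
      blocks <- split(seq_len(d), rep(seq_len(k), each = ceiling(d / k),
                                      length.out = d))
      for (j in seq_len(k)) {
        a_true[j, blocks[[j]]] <- stats::rnorm(length(blocks[[j]]), 0,
                                               config$weight_scale)
      }
    } else {
      a_true[] <- stats::rnorm(k * d, 0, config$weight_scale)
    }
  }
  structure(list(z_true = z_true, a_true = a_true,
                 noise_sd = config$noise_sd,
                 membership_probs = config$membership_probs,
                 config = config),
            class = "planted_model")
}

#' Generate a raw battery from a planted model
#'
#' `values = z_true a_true + N(0, noise_sd^2)` noise per cell, then each
#' cell is masked independently with probability `missing_rate`. With
#' `config$raw_shift`, each measure is additionally shifted and scaled
#' (location `N(0, 10^2)`, scale `Unif(0.5, 3)`) so the battery arrives on
#' an instrument-like raw scale and the preprocessing stage has real work
#' to do.
#'
#' @param planted A [plant_model()] result.
#' @param config A [synthetic_config()]; defaults to the one stored in
#'   `planted`.
#' @param seed Seed for the noise/mask draws. Default `config$seed + 1`.
#' @return A [raw_battery()]. The model-scale matrix (before any raw shift)
#'   is attached as attribute `"model_scale_values"`.
#' @export
generate_battery <- function(planted, config = planted$config,
                             seed = config$seed + 1L) {
  stopifnot(inherits(planted, "planted_model"))
  set.seed(seed)
  n <- config$n_participants; d <- config$n_measures
  latent <- planted$z_true %*% planted$a_true +
    matrix(stats::rnorm(n * d, 0, config$noise_sd), n, d)
  mask <- matrix(stats::runif(n * d) >= config$missing_rate, n, d)
  values <- latent
  if (config$raw_shift) {
    loc <- stats::rnorm(d, 0, 10)
    scale <- stats::runif(d, 0.5, 3)
    # the finger-tapping measure gets an instrument-realistic range so the
    # plausibility filter ([10, 151] taps) sees data on its own scale
    tap <- match("cnb_finger_tapping", synthetic_schema(d)$measure_id)
    if (!is.na(tap)) {
      loc[tap] <- 80
      scale[tap] <- 10
    }
    values <- sweep(sweep(values, 2, scale, "*"), 2, loc, "+")
  }
  values[!mask] <- NA_real_
  b <- raw_battery(values, sprintf("p%04d", seq_len(n)),
                   synthetic_schema(d), mask)
  attr(b, "model_scale_values") <- latent
  b
}

#' Generate outcomes with target correlations to planted features
#'
#' Each outcome is `sum_k beta_k z_true[, k] + N(0, noise)` with `beta_k`
#' and the noise SD solved so the population correlation between the
#' outcome and planted membership indicator `k` equals the spec's `rho_k`:
#' with membership variance `v_k = p_k (1 - p_k)` and unit total outcome
#' variance, `beta_k = rho_k / sqrt(v_k)` and noise variance
#' `1 - sum(rho_k^2)` (memberships are independent). A spec with
#' `sum(rho^2) >= 1` is infeasible and rejected.
#'
#' @param planted A [plant_model()] result.
#' @param config A [synthetic_config()].
#' @param seed Seed for the outcome noise. Default `config$seed + 2`.
#' @return An [outcome_table()].
#' @export
generate_outcomes <- function(planted, config = planted$config,
                              seed = config$seed + 2L) {
  stopifnot(inherits(planted, "planted_model"))
  set.seed(seed)
  n <- config$n_participants
  k <- config$planted_k
  v <- config$membership_probs * (1 - config$membership_probs)
  out <- matrix(NA_real_, n, length(config$outcome_specs))
  fams <- character(length(config$outcome_specs))
  nm <- character(length(config$outcome_specs))
  for (idx in seq_along(config$outcome_specs)) {
    os <- config$outcome_specs[[idx]]
    noise_var <- 1 - sum(os$rho^2)
    if (noise_var <= 0) {
      stop("outcome spec '", os$name,
           "' is infeasible: sum(rho^2) must be < 1", call. = FALSE)
    }
    beta <- if (k > 0) os$rho / sqrt(v) else numeric(0)
    signal <- if (k > 0) drop(planted$z_true %*% beta) else rep(0, n)
    out[, idx] <- signal + stats::rnorm(n, 0, sqrt(noise_var))
    fams[idx] <- os$family
    nm[idx] <- os$name
  }
  colnames(out) <- nm
  names(fams) <- nm
  outcome_table(out, sprintf("p%04d", seq_len(n)), fams)
}

#' Generate a demographics table
#'
#' Ages are uniform integers on 18–55 (the study's inclusion band); sex and
#' race/ethnicity are categorical draws with configurable proportions. The
#' table is independent of the planted features by construction, so
#' demographic balance tests are calibrated under the null.
#'
#' @param n Number of participants.
#' @param seed Integer seed.
#' @param sex_probs,race_probs Named probability vectors.
#' @return A data frame: `participant_id`, `age`, `sex`, `race_ethnicity`.
#' @export
generate_demographics <- function(n, seed = 1L,
                                  sex_probs = c(female = 0.64, male = 0.36),
                                  race_probs = c(white = 0.67, black = 0.21,
                                                 asian = 0.06,
                                                 other = 0.06)) {
  stopifnot(n >= 1)
  set.seed(seed)
  data.frame(participant_id = sprintf("p%04d", seq_len(n)),
             age = sample(18:55, n, replace = TRUE),
             sex = sample(names(sex_probs), n, replace = TRUE,
                          prob = sex_probs),
             race_ethnicity = sample(names(race_probs), n, replace = TRUE,
                                     prob = race_probs),
             stringsAsFactors = FALSE)
}

#' Generate a full synthetic dataset
#'
#' Convenience wrapper drawing the planted model, battery, outcomes and
#' demographics from one config; all components share participant ids and
#' are deterministic functions of `(config, config$seed)`.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_dataset`: `battery` ([raw_battery()]),
#'   `outcomes` ([outcome_table()]), `demographics`, `planted`
#'   ([plant_model()]), `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  planted <- plant_model(config)
  structure(list(battery = generate_battery(planted, config),
                 outcomes = generate_outcomes(planted, config),
                 demographics = generate_demographics(
                   config$n_participants, config$seed + 3L,
                   config$sex_probs, config$race_probs),
                 planted = planted, config = config),
            class = "synthetic_dataset")
}

# rank (Mann-Whitney) AUC of score against binary truth; NA when one class
# is empty
membership_auc <- function(score, truth) {
  pos <- score[truth == 1]
  neg <- score[truth == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Recovery report: fitted features against the planted truth
#'
#' Matches the fit's retained features to the planted features by maximal
#' total cosine similarity of weight vectors, then reports: modal `K` over
#' the trace tail (last half of sweeps) vs `planted_k`; per matched feature,
#' the membership AUC (continuous feature values against `z_true`) and the
#' Pearson correlation of weight vectors; and the relative `sigma_x` error.
#' The report is a pure function of its inputs.
#'
#' @param dataset A [generate_dataset()] result (or a list with `planted`).
#' @param fit An `ibp_fit` from [run_ibp()] on the dataset's battery.
#' @param values Optional `continuous_feature_values`; computed from the fit
#'   and the dataset battery when omitted.
#' @param battery Battery the fit was produced from; defaults to the
#'   dataset's model-scale battery.
#' @return A list of class `recovery_report`: `modal_k`, `planted_k`,
#'   `n_retained` (features passing the 5%-of-sample count filter — the
#'   interpretable-feature count, robust to low-count transients),
#'   `matches` (data frame: fitted feature, planted feature, cosine
#'   similarity, membership AUC, weight correlation), `sigma_x_hat`,
#'   `sigma_x_true`, `sigma_x_rel_error`.
#' @export
recovery_report <- function(dataset, fit, values = NULL, battery = NULL) {
  planted <- dataset$planted
  if (is.null(battery)) battery <- dataset$battery
  if (is.null(values)) values <- continuous_feature_values(fit$state, battery)
  tail_k <- fit$trace$k[-seq_len(ceiling(nrow(fit$trace) / 2))]
  modal_k <- as.integer(names(which.max(table(tail_k))))
  a_fit <- fit$state$a
  k_fit <- nrow(a_fit)
  matches <- data.frame(fitted = integer(0), planted = integer(0),
                        similarity = numeric(0), auc = numeric(0),
                        weight_cor = numeric(0))
  if (k_fit > 0 && dataset$config$planted_k > 0) {
    mm <- match_features(a_fit, planted$a_true)
    matches <- data.frame(fitted = mm$feature_1, planted = mm$feature_2,
                          similarity = mm$similarity,
                          auc = NA_real_, weight_cor = NA_real_)
    for (i in seq_len(nrow(matches))) {
      kf <- matches$fitted[i]; kp <- matches$planted[i]
      matches$auc[i] <- membership_auc(values$values[, kf],
                                       planted$z_true[, kp])
      matches$weight_cor[i] <- stats::cor(a_fit[kf, ], planted$a_true[kp, ])
    }
  }
  sx_hat <- fit$state$sigma_x
  n_retained <- length(filter_features(
    fit$state$z, inclusion_threshold(nrow(fit$state$z), 0.05))$retained)
  structure(list(modal_k = modal_k, planted_k = dataset$config$planted_k,
                 n_retained = n_retained,
                 matches = matches, sigma_x_hat = sx_hat,
                 sigma_x_true = planted$noise_sd,
                 sigma_x_rel_error =
                   abs(sx_hat - planted$noise_sd) / planted$noise_sd),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> modal K = %d, retained K = %d (planted %d)\n",
              x$modal_k, x$n_retained, x$planted_k))
  cat(sprintf("  sigma_x: %.3f vs planted %.3f (rel. error %.1f%%)\n",
              x$sigma_x_hat, x$sigma_x_true, 100 * x$sigma_x_rel_error))
  if (nrow(x$matches) > 0) {
    cat(sprintf("  matched AUCs: %s\n",
                paste(sprintf("%.3f", x$matches$auc), collapse = ", ")))
  }
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes the battery, outcomes and demographics as CSV and the ground truth
#' (`z_true`, `a_true`, config) as JSON, for use by external harnesses.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(battery = file.path(dir, "battery.csv"),
             outcomes = file.path(dir, "outcomes.csv"),
             demographics = file.path(dir, "demographics.csv"),
             truth = file.path(dir, "ground_truth.json"))
  b <- dataset$battery
  utils::write.csv(data.frame(participant_id = b$participant_ids, b$values,
                              check.names = FALSE),
                   paths["battery"], row.names = FALSE, na = "")
  o <- dataset$outcomes
  utils::write.csv(data.frame(participant_id = o$participant_ids, o$values,
                              check.names = FALSE),
                   paths["outcomes"], row.names = FALSE, na = "")
  utils::write.csv(dataset$demographics, paths["demographics"],
                   row.names = FALSE)
  cfg <- dataset$config
  jsonlite::write_json(list(z_true = dataset$planted$z_true,
                            a_true = dataset$planted$a_true,
                            noise_sd = cfg$noise_sd,
                            membership_probs = cfg$membership_probs,
                            families = as.list(o$families),
                            seed = cfg$seed),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
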