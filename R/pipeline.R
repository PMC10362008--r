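#' Tabulate multi-feature sampling combinations
#'
#' For each participant, the set of features sampled at the final iteration;
#' returns the frequency of each distinct combination (the empty combination
#' included).
#'
#' @param z Final-state binary matrix (or `continuous_feature_values`).
#' @return A data frame: `combination` (e.g. `""`, `"1"`, `"1+3"`), `size`,
#'   `count`, sorted by decreasing count. Counts sum to N.
#' @export
multi_feature_report <- function(z) {
  if (inherits(z, "continuous_feature_values")) z <- z$z
  z <- as.matrix(z)
  combos <- apply(z, 1, function(row) paste(which(row == 1), collapse = "+"))
  tab <- table(combos)
  out <- data.frame(combination = names(tab),
                    size = vapply(strsplit(names(tab), "\\+"), length,
                                  integer(1)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out[order(-out$count, out$combination), , drop = FALSE]
}

#' Run the full analysis pipeline
#'
#' Executes, in order: preprocessing (direction conventions, finger-tapping
#' filter, z-scoring), the IBP sampler, feature filtering and profiling,
#' demographic balance tests (when demographics are supplied), and the
#' outcome correlation / dependent-comparison stage (when outcomes are
#' supplied and at least two features are retained). All randomness flows
#' from a single seed, deterministically split into per-stage seeds. When
#' `outdir` is given, writes the trace, filter report, profile table,
#' correlation and comparison tables, demographic report, combination counts
#' and a JSON run manifest.
#'
#' @param battery A [raw_battery()] (real data path) — or `NULL` with
#'   `synthetic` supplied.
#' @param outcomes Optional [outcome_table()].
#' @param demographics Optional demographics data frame (see
#'   [demographic_tests()]).
#' @param synthetic Optional [synthetic_config()]; generates battery,
#'   outcomes and demographics in place of real inputs. Exactly one of
#'   `battery` / `synthetic` must be supplied.
#' @param sweeps,hypers,k_cap Sampler settings, see [run_ibp()].
#' @param filter_fraction Retention fraction. Default 0.05.
#' @param method Dependent-comparison statistic. Default `"steiger"`.
#' @param alpha Significance level for adjusted flags. Default 0.05.
#' @param seed Single integer seed for the run. Default 1.
#' @param outdir Optional output directory for CSV/JSON artifacts.
#' @return A list of class `pipeline_result`: `standardized`, `fit`,
#'   `values`, `filter`, `profiles`, `demographic_report`, `comparison`,
#'   `combinations`, `manifest`.
#' @export
run_pipeline <- function(battery = NULL, outcomes = NULL,
                         demographics = NULL, synthetic = NULL,
                         sweeps = 50, hypers = NULL,
                         k_cap = 4, filter_fraction = 0.05,
                         method = "steiger", alpha = 0.05, seed = 1L,
                         outdir = NULL) {
  if (is.null(battery) == is.null(synthetic)) {
    stop("supply exactly one of `battery` or `synthetic`", call. = FALSE)
  }
  t0 <- Sys.time()
  stage_seed <- function(offset) as.integer((seed * 1000L + offset) %% .Machine$integer.max)
  if (!is.null(synthetic)) {
    synthetic$seed <- stage_seed(0)
    dataset <- generate_dataset(synthetic)
    battery <- dataset$battery
    if (is.null(outcomes)) outcomes <- dataset$outcomes
    if (is.null(demographics)) demographics <- dataset$demographics
  }
  std <- preprocess_battery(battery)
  if (!is.null(outcomes) &&
      !identical(std$participant_ids, outcomes$participant_ids)) {
    bad <- union(setdiff(std$participant_ids, outcomes$participant_ids),
                 setdiff(outcomes$participant_ids, std$participant_ids))
    stop("alignment error between battery and outcomes; offending ids: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  fit <- run_ibp(std, sweeps = sweeps, seed = stage_seed(1),
                 hypers = hypers, k_cap = k_cap)
  values <- continuous_feature_values(fit$state, std)
  threshold <- inclusion_threshold(length(std$participant_ids),
                                   filter_fraction)
  filt <- filter_features(values$z, threshold)
  profiles <- if (length(filt$retained) > 0) {
    feature_profiles(std, values$z, filt$retained)
  } else NULL
  demo_report <- if (!is.null(demographics) && length(filt$retained) > 0) {
    demographic_tests(values$z, demographics, filt$retained)
  } else NULL
  comparison <- NULL
  if (!is.null(outcomes) && length(filt$retained) >= 2) {
    comparison <- build_comparison_table(values, outcomes,
                                         retained = filt$retained,
                                         method = method, alpha = alpha)
  }
  combinations <- multi_feature_report(values$z)
  manifest <- list(
    seed = seed, sweeps = sweeps, k_cap = k_cap,
    filter_fraction = filter_fraction, method = method, alpha = alpha,
    synthetic = !is.null(synthetic),
    n_participants = length(std$participant_ids),
    n_measures = ncol(std$values),
    final_k = ncol(fit$state$z), threshold = threshold,
    retained = length(filt$retained),
    package_version = as.character(utils::packageVersion("ibpcog")),
    elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  result <- structure(list(standardized = std, fit = fit, values = values,
                           filter = filt, profiles = profiles,
                           demographic_report = demo_report,
                           comparison = comparison,
                           combinations = combinations, manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline_result(result, outdir)
  result
}

#' Write pipeline artifacts to a directory
#'
#' @param result A `pipeline_result`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_pipeline_result <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_trace(result$fit, file.path(outdir, "trace.csv"))
  utils::write.csv(data.frame(feature_id = names(result$filter$counts),
                              count = result$filter$counts,
                              retained = seq_along(result$filter$counts)
                              %in% result$filter$retained,
                              row.names = NULL),
                   file.path(outdir, "feature_filter.csv"),
                   row.names = FALSE)
  vals <- data.frame(participant_id = result$standardized$participant_ids,
                     result$values$values)
  names(vals)[-1] <- result$values$feature_ids
  utils::write.csv(vals, file.path(outdir, "feature_values.csv"),
                   row.names = FALSE)
  if (!is.null(result$profiles)) {
    utils::write.csv(result$profiles,
                     file.path(outdir, "feature_profiles.csv"),
                     row.names = FALSE)
  }
  if (!is.null(result$demographic_report)) {
    utils::write.csv(result$demographic_report,
                     file.path(outdir, "demographic_tests.csv"),
                     row.names = FALSE)
  }
  if (!is.null(result$comparison)) {
    utils::write.csv(result$comparison$correlations,
                     file.path(outdir, "correlations.csv"),
                     row.names = FALSE)
    utils::write.csv(result$comparison$comparisons,
                     file.path(outdir, "comparisons.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(result$combinations,
                   file.path(outdir, "feature_combinations.csv"),
                   row.names = FALSE)
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(result$manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest_path)
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0("<pipeline_result> N = %d, D = %d: final K = %d, ",
                     "%d feature(s) retained (threshold %d)\n"),
              m$n_participants, m$n_measures, m$final_k, m$retained,
              m$threshold))
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
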