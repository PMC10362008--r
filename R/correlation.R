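#' Behavioral outcome table
#'
#' Holds participant-aligned outcome columns (e.g. impulsivity subscales,
#' an externalizing t-score, substance-use scores) with a family label per
#' outcome used for family-wise Bonferroni correction.
#'
#' @param values Numeric N x M matrix or data frame of outcomes; `NA` marks
#'   missing.
#' @param participant_ids Character vector of length N, aligned with the
#'   battery.
#' @param families Named character vector mapping each outcome name to
#'   `"impulsive_behavior"` or `"substance_use"`.
#' @return An object of class `outcome_table`.
#' @export
outcome_table <- function(values, participant_ids, families) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values))) {
    stop("outcome columns must be named", call. = FALSE)
  }
  if (length(participant_ids) != nrow(values)) {
    stop("participant_ids length does not match row count", call. = FALSE)
  }
  missing_fam <- setdiff(colnames(values), names(families))
  if (length(missing_fam) > 0) {
    stop("no family label for outcome(s): ",
         paste(missing_fam, collapse = ", "), call. = FALSE)
  }
  allowed <- c("impulsive_behavior", "substance_use")
  bad <- setdiff(unique(families), allowed)
  if (length(bad) > 0) {
    stop("unknown family label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(values = values, mask = !is.na(values),
                 participant_ids = as.character(participant_ids),
                 families = families[colnames(values)]),
            class = "outcome_table")
}

#' Load an outcome table from a delimited file
#'
#' @param path CSV/TSV path with a participant-id column and numeric outcome
#'   columns; empty cells mean missing.
#' @param families Named character vector of family labels (see
#'   [outcome_table()]); outcomes absent from `families` are dropped with a
#'   warning.
#' @param id_col Participant-id column name.
#' @return An [outcome_table()].
#' @export
load_outcomes <- function(path, families, id_col = "participant_id") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", "NA"), check.names = FALSE)
  if (!id_col %in% names(df)) {
    stop("file is missing the participant-id column '", id_col, "'",
         call. = FALSE)
  }
  ids <- as.character(df[[id_col]])
  keep <- intersect(names(df), names(families))
  dropped <- setdiff(setdiff(names(df), id_col), keep)
  if (length(dropped) > 0) {
    warning("dropping outcome column(s) without family label: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  outcome_table(as.matrix(df[, keep, drop = FALSE]), ids, families)
}

#' Pairwise-complete Pearson correlation
#'
#' Computes the Pearson correlation over jointly observed pairs of `a` and
#' `b` (`NA` = missing), with the two-sided p-value from the t transform
#' `t = r sqrt((n - 2) / (1 - r^2))` (as in [stats::cor.test()], which this
#' wraps).
#'
#' @param a,b Numeric vectors of equal length.
#' @return A list of class `correlation_estimate`: `r`, `n_effective`, `p`.
#' @export
pearson_pairwise <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n < 3) {
    stop("undefined correlation: fewer than 3 jointly observed pairs",
         call. = FALSE)
  }
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
    stop("undefined correlation: zero variance on the joint sample",
         call. = FALSE)
  }
  ct <- stats::cor.test(a[ok], b[ok], method = "pearson")
  structure(list(r = unname(ct$estimate), n_effective = n, p = ct$p.value),
            class = "correlation_estimate")
}

# validity check: the 3x3 correlation matrix of (j, k, y) must be positive
# semidefinite
check_correlation_triple <- function(r_jy, r_ky, r_jk) {
  rs <- c(r_jy, r_ky, r_jk)
  if (any(!is.finite(rs)) || any(abs(rs) >= 1)) {
    stop("degenerate input: correlations must lie strictly in (-1, 1)",
         call. = FALSE)
  }
  det3 <- 1 - r_jy^2 - r_ky^2 - r_jk^2 + 2 * r_jy * r_ky * r_jk
  if (det3 < -1e-12) {
    stop("invalid correlation triple: the implied 3x3 matrix is not ",
         "positive semidefinite", call. = FALSE)
  }
  invisible(det3)
}

#' Compare two overlapping dependent correlations
#'
#' Tests `H0: rho_jy = rho_ky` for two correlations sharing the variable `y`
#' and computed on the same sample of size `n`; the dependence between the
#' two estimates is driven by `r_jk`. Methods:
#' \describe{
#'   \item{`"steiger"` (default)}{Dunn–Clark-type z on Fisher-transformed
#'     correlations with the covariance term evaluated at the average of
#'     `r_jy` and `r_ky` (Steiger 1980):
#'     `z = (z_jy - z_ky) sqrt((n - 3) / (2 - 2 c))`, two-sided p from the
#'     standard normal.}
#'   \item{`"williams"`}{Williams' t with `n - 3` degrees of freedom.}
#'   \item{`"zou"`}{Zou's confidence interval for `r_jy - r_ky`; the
#'     statistic is the difference, `p` is `NA`, and `ci_lower`/`ci_upper`
#'     plus `significant` (0 outside the interval) are returned.}
#' }
#' The statistic is antisymmetric under swapping `j` and `k`; `p` is
#' invariant.
#'
#' @param r_jy,r_ky Correlations of features j and k with the shared outcome.
#' @param r_jk Correlation between the two features.
#' @param n Common sample size (>= 4).
#' @param method One of `"steiger"`, `"williams"`, `"zou"`.
#' @param conf_level Confidence level for `method = "zou"`. Default 0.95.
#' @return A list of class `dependent_comparison`: `statistic`, `p`,
#'   `method`, `n`, and for `"zou"` also `ci_lower`, `ci_upper`,
#'   `significant`.
#' @export
dependent_overlapping_test <- function(r_jy, r_ky, r_jk, n,
                                       method = c("steiger", "williams",
                                                  "zou"),
                                       conf_level = 0.95) {
  method <- match.arg(method)
  stopifnot(n >= 4)
  check_correlation_triple(r_jy, r_ky, r_jk)
  out <- switch(method,
    steiger = {
      rbar <- (r_jy + r_ky) / 2
      cov_term <- (r_jk * (1 - 2 * rbar^2) -
                     0.5 * rbar^2 * (1 - 2 * rbar^2 - r_jk^2)) /
        (1 - rbar^2)^2
      z <- (atanh(r_jy) - atanh(r_ky)) * sqrt((n - 3) / (2 - 2 * cov_term))
      list(statistic = z, p = 2 * stats::pnorm(-abs(z)))
    },
    williams = {
      kdet <- 1 - r_jy^2 - r_ky^2 - r_jk^2 + 2 * r_jy * r_ky * r_jk
      denom <- 2 * kdet * (n - 1) / (n - 3) +
        ((r_jy + r_ky)^2 / 4) * (1 - r_jk)^3
      tstat <- (r_jy - r_ky) * sqrt((n - 1) * (1 + r_jk)) / sqrt(denom)
      list(statistic = tstat, p = 2 * stats::pt(-abs(tstat), df = n - 3))
    },
    zou = {
      zcrit <- stats::qnorm(1 - (1 - conf_level) / 2)
      hw <- zcrit / sqrt(n - 3)
      l1 <- tanh(atanh(r_jy) - hw); u1 <- tanh(atanh(r_jy) + hw)
      l2 <- tanh(atanh(r_ky) - hw); u2 <- tanh(atanh(r_ky) + hw)
      corr_r <- ((r_jk - 0.5 * r_jy * r_ky) *
                   (1 - r_jy^2 - r_ky^2 - r_jk^2) + r_jk^3) /
        ((1 - r_jy^2) * (1 - r_ky^2))
      diff <- r_jy - r_ky
      lower <- diff - sqrt((r_jy - l1)^2 + (u2 - r_ky)^2 -
                             2 * corr_r * (r_jy - l1) * (u2 - r_ky))
      upper <- diff + sqrt((u1 - r_jy)^2 + (r_ky - l2)^2 -
                             2 * corr_r * (u1 - r_jy) * (r_ky - l2))
      list(statistic = diff, p = NA_real_, ci_lower = lower,
           ci_upper = upper, significant = (lower > 0 | upper < 0))
    })
  structure(c(out, list(method = method, n = n)),
            class = "dependent_comparison")
}

#' Bonferroni adjustment by outcome-family size
#'
#' Multiplies a p-value by the number of measures in the outcome's family
#' and caps at 1. The default family sizes are 2 for impulsive-behavior
#' measures and 4 for substance-use measures.
#'
#' @param p P-value(s).
#' @param m Family size (>= 1).
#' @return `pmin(1, m * p)`.
#' @export
bonferroni_adjust <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, m * p)
}

#' Default Bonferroni family sizes
#' @return Named integer vector: impulsive_behavior = 2, substance_use = 4.
#' @export
default_family_sizes <- function() {
  c(impulsive_behavior = 2L, substance_use = 4L)
}

#' Correlate feature values with outcomes and compare features pairwise
#'
#' For every outcome: the Pearson correlation between each retained
#' feature's continuous values and the outcome; and, for every pair of
#' retained features, an overlapping dependent-correlation test computed on
#' the subsample jointly observed on both features and the outcome (so the
#' correlation triple is internally consistent). P-values are Bonferroni
#' adjusted by the outcome's family size.
#'
#' @param values A `continuous_feature_values` object, or an N x K numeric
#'   matrix of feature values.
#' @param outcomes An [outcome_table()].
#' @param retained Indices of retained features (>= 2); default all.
#' @param method Comparison statistic, see [dependent_overlapping_test()].
#' @param family_sizes Named vector of Bonferroni family sizes; default
#'   [default_family_sizes()].
#' @param alpha Significance level for the adjusted flags. Default 0.05.
#' @return A list of class `comparison_table`:
#'   `correlations` (outcome x feature long data frame: r, n, p),
#'   `comparisons` (long data frame: outcome, feature_j, feature_k, r_jy,
#'   r_ky, r_jk, statistic, p, bonferroni_m, p_adjusted,
#'   significant_adjusted), `excluded_outcomes`.
#' @export
build_comparison_table <- function(values, outcomes, retained = NULL,
                                   method = "steiger",
                                   family_sizes = default_family_sizes(),
                                   alpha = 0.05) {
  if (inherits(values, "continuous_feature_values")) values <- values$values
  values <- as.matrix(values)
  stopifnot(inherits(outcomes, "outcome_table"))
  if (nrow(values) != nrow(outcomes$values)) {
    stop("alignment error: feature values have ", nrow(values),
         " rows but outcomes have ", nrow(outcomes$values), call. = FALSE)
  }
  if (is.null(retained)) retained <- seq_len(ncol(values))
  if (length(retained) < 2) {
    stop("need at least 2 retained features to compare", call. = FALSE)
  }
  feat_ids <- paste0("feature_", retained)
  cors <- list(); comps <- list(); excluded <- character(0)
  for (o in colnames(outcomes$values)) {
    y <- outcomes$values[, o]
    if (all(is.na(y))) {
      warning("outcome '", o, "' has no observed values; excluded",
              call. = FALSE)
      excluded <- c(excluded, o)
      next
    }
    fam <- outcomes$families[[o]]
    m_fam <- unname(family_sizes[[fam]])
    for (idx in seq_along(retained)) {
      pc <- pearson_pairwise(values[, retained[idx]], y)
      cors[[length(cors) + 1]] <- data.frame(
        outcome = o, family = fam, feature_id = feat_ids[idx], r = pc$r,
        n = pc$n_effective, p = pc$p,
        p_adjusted = bonferroni_adjust(pc$p, m_fam),
        stringsAsFactors = FALSE)
    }
    pairs <- utils::combn(seq_along(retained), 2, simplify = FALSE)
    for (pr in pairs) {
      j <- retained[pr[1]]; k <- retained[pr[2]]
      vj <- values[, j]; vk <- values[, k]
      ok <- !is.na(vj) & !is.na(vk) & !is.na(y)
      n <- sum(ok)
      if (n < 4) next
      r_jy <- stats::cor(vj[ok], y[ok])
      r_ky <- stats::cor(vk[ok], y[ok])
      r_jk <- stats::cor(vj[ok], vk[ok])
      identical_features <- isTRUE(all.equal(vj[ok], vk[ok]))
      if (identical_features) {
        stat <- 0; p <- 1; r_jk <- 1; p_adj <- 1; sig <- FALSE
      } else if (method == "zou") {
        # Bonferroni for the interval method: widen to level 1 - alpha / m
        tst <- dependent_overlapping_test(r_jy, r_ky, r_jk, n, "zou",
                                          conf_level = 1 - alpha / m_fam)
        stat <- tst$statistic
        p <- NA_real_; p_adj <- NA_real_
        sig <- tst$significant
      } else {
        tst <- dependent_overlapping_test(r_jy, r_ky, r_jk, n, method)
        stat <- tst$statistic
        p <- tst$p
        p_adj <- bonferroni_adjust(p, m_fam)
        sig <- p_adj < alpha
      }
      comps[[length(comps) + 1]] <- data.frame(
        outcome = o, family = fam,
        feature_j = feat_ids[pr[1]], feature_k = feat_ids[pr[2]],
        r_jy = r_jy, r_ky = r_ky, r_jk = r_jk, n = n,
        statistic = stat, p = p, bonferroni_m = m_fam, p_adjusted = p_adj,
        significant_adjusted = sig, stringsAsFactors = FALSE)
    }
  }
  structure(list(correlations = do.call(rbind, cors),
                 comparisons = do.call(rbind, comps),
                 excluded_outcomes = excluded, method = method,
                 alpha = alpha),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  nsig <- sum(x$comparisons$significant_adjusted, na.rm = TRUE)
  cat(sprintf(paste0("<comparison_table> %d correlation(s), %d pairwise ",
                     "comparison(s) [%s], %d significant after Bonferroni\n"),
              nrow(x$correlations), nrow(x$comparisons), x$method, nsig))
  if (length(x$excluded_outcomes) > 0) {
    cat("  excluded outcomes:",
        paste(x$excluded_outcomes, collapse = ", "), "\n")
  }
  invisible(x)
}
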