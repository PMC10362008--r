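#' Minimum member count for feature retention
#'
#' Converts a retention fraction into a member-count threshold:
#' `floor(fraction * n)`. With a sample of 673 and the default 5% fraction
#' this gives 33, i.e. "features sampled by at least 33 people".
#'
#' @param n Sample size (>= 1).
#' @param fraction Retention fraction in (0, 1). Default 0.05.
#' @return Integer threshold.
#' @examples
#' inclusion_threshold(673, 0.05)  # 33
#' @export
inclusion_threshold <- function(n, fraction = 0.05) {
  stopifnot(n >= 1)
  if (!(is.numeric(fraction) && length(fraction) == 1 &&
        fraction > 0 && fraction < 1)) {
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  as.integer(floor(fraction * n))
}

#' Filter features by final-iteration sampling count
#'
#' Retains exactly the features whose member count (column sum of the
#' final-iteration binary matrix) is at least `threshold`. Counts are
#' reported for all features, retained or dropped.
#'
#' @param z Binary N x K matrix (or a `continuous_feature_values` object,
#'   whose `$z` is used).
#' @param threshold Integer minimum member count.
#' @return A list of class `feature_filter_result`: `threshold_count`,
#'   `counts` (named integer vector over all features), `retained`
#'   (indices), `retained_feature_ids`.
#' @export
filter_features <- function(z, threshold) {
  if (inherits(z, "continuous_feature_values")) z <- z$z
  z <- as.matrix(z)
  counts <- as.integer(colSums(z))
  ids <- sprintf("feature_%d", seq_len(ncol(z)))
  names(counts) <- ids
  retained <- unname(which(counts >= threshold))
  structure(list(threshold_count = as.integer(threshold), counts = counts,
                 retained = retained, retained_feature_ids = ids[retained]),
            class = "feature_filter_result")
}

#' @export
print.feature_filter_result <- function(x, ...) {
  cat(sprintf("<feature_filter_result> %d of %d features with count >= %d\n",
              length(x$retained), length(x$counts), x$threshold_count))
  invisible(x)
}

#' Profile one feature as per-measure mean z-scores
#'
#' For the members of a feature, computes each measure's mean z-score and
#' standard error (SD over contributing cells divided by the square root of
#' their count) using unmasked cells only. With a single contributing cell
#' the SE is reported as `NA`.
#'
#' @param battery A `standardized_battery`.
#' @param members Integer or logical index of the feature's members
#'   (nonempty).
#' @param feature_id Optional label attached to the output.
#' @return A data frame with columns `feature_id`, `measure_id`, `mean_z`,
#'   `se`, `n_cells`, plus attribute `member_count`.
#' @export
summarize_feature <- function(battery, members, feature_id = "feature_1") {
  stopifnot(inherits(battery, "ncog_battery"))
  if (is.logical(members)) members <- which(members)
  if (length(members) == 0) stop("member set is empty", call. = FALSE)
  v <- battery$values[members, , drop = FALSE]
  m <- battery$mask[members, , drop = FALSE]
  d <- ncol(v)
  mean_z <- se <- rep(NA_real_, d)
  n_cells <- integer(d)
  for (j in seq_len(d)) {
    obs <- v[m[, j], j]
    n_cells[j] <- length(obs)
    if (n_cells[j] >= 1) mean_z[j] <- mean(obs)
    if (n_cells[j] >= 2) se[j] <- stats::sd(obs) / sqrt(n_cells[j])
  }
  out <- data.frame(feature_id = feature_id,
                    measure_id = battery$schema$measure_id,
                    mean_z = mean_z, se = se, n_cells = n_cells,
                    stringsAsFactors = FALSE)
  attr(out, "member_count") <- length(members)
  out
}

#' Profile all retained features
#'
#' @param battery A `standardized_battery`.
#' @param z Final-iteration binary matrix (or `continuous_feature_values`).
#' @param retained Integer indices of retained features (e.g. from
#'   [filter_features()]); defaults to all nonempty features.
#' @return A long data frame (feature x measure) of [summarize_feature()]
#'   rows, with a `member_count` column.
#' @export
feature_profiles <- function(battery, z, retained = NULL) {
  if (inherits(z, "continuous_feature_values")) z <- z$z
  z <- as.matrix(z)
  if (is.null(retained)) retained <- which(colSums(z) > 0)
  rows <- lapply(retained, function(k) {
    p <- summarize_feature(battery, z[, k] == 1, paste0("feature_", k))
    p$member_count <- attr(p, "member_count")
    p
  })
  do.call(rbind, rows)
}

#' Demographic balance tests for feature membership
#'
#' For each retained feature, compares members with non-members: a one-way
#' analysis-of-variance F test for age, and chi-square tests of independence
#' (without continuity correction) for each categorical variable (sex,
#' race/ethnicity). A test whose expected table contains a zero cell is
#' skipped with a warning.
#'
#' @param z Binary N x K matrix (or `continuous_feature_values`).
#' @param demographics Data frame aligned to participants with a numeric
#'   `age` column and categorical columns (default `sex`,
#'   `race_ethnicity`).
#' @param retained Feature indices to test; default all nonempty.
#' @param categorical Names of categorical columns to test.
#' @return Data frame: `feature_id`, `variable`, `test`, `statistic`, `df`,
#'   `p`.
#' @export
demographic_tests <- function(z, demographics, retained = NULL,
                              categorical = c("sex", "race_ethnicity")) {
  if (inherits(z, "continuous_feature_values")) z <- z$z
  z <- as.matrix(z)
  stopifnot(nrow(z) == nrow(demographics))
  if (is.null(retained)) retained <- which(colSums(z) > 0)
  categorical <- intersect(categorical, names(demographics))
  out <- list()
  for (k in retained) {
    membership <- factor(z[, k], levels = c(0, 1),
                         labels = c("non-member", "member"))
    fid <- paste0("feature_", k)
    if ("age" %in% names(demographics)) {
      fit <- stats::aov(demographics$age ~ membership)
      tab <- summary(fit)[[1]]
      out[[length(out) + 1]] <- data.frame(
        feature_id = fid, variable = "age", test = "anova_f",
        statistic = tab[["F value"]][1], df = tab[["Df"]][1],
        p = tab[["Pr(>F)"]][1], stringsAsFactors = FALSE)
    }
    for (v in categorical) {
      tab <- table(membership, demographics[[v]])
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected == 0)) {
        warning("skipping chi-square for '", v, "' on ", fid,
                ": zero expected cell count", call. = FALSE)
        next
      }
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      out[[length(out) + 1]] <- data.frame(
        feature_id = fid, variable = v, test = "chi_square",
        statistic = unname(ct$statistic), df = unname(ct$parameter),
        p = ct$p.value, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# cosine similarity between columns... rows of two matrices
cosine_similarity_matrix <- function(a1, a2) {
  n1 <- sqrt(rowSums(a1^2))
  n2 <- sqrt(rowSums(a2^2))
  s <- (a1 %*% t(a2)) / (n1 %o% n2)
  s[!is.finite(s)] <- 0
  s
}

# maximize total similarity under a one-to-one assignment. Exact by
# permutation enumeration when the smaller side has <= 8 rows, greedy
# otherwise. Returns an integer map: for each row of the smaller side, the
# assigned row of the larger side.
assign_one_to_one <- function(sim) {
  transposed <- nrow(sim) > ncol(sim)
  if (transposed) sim <- t(sim)
  n1 <- nrow(sim); n2 <- ncol(sim)
  if (n1 == 0) return(list(map = integer(0), transposed = transposed))
  if (n1 <= 8 && choose(n2, n1) * factorial(n1) <= 2e5) {
    perms <- function(v) {
      if (length(v) <= 1) return(matrix(v, ncol = length(v)))
      do.call(rbind, lapply(seq_along(v), function(i) {
        cbind(v[i], perms(v[-i]))
      }))
    }
    best <- NULL; best_val <- -Inf
    combs <- utils::combn(n2, n1, simplify = FALSE)
    for (cc in combs) {
      pp <- perms(cc)
      vals <- apply(pp, 1, function(p) sum(sim[cbind(seq_len(n1), p)]))
      if (max(vals) > best_val) {
        best_val <- max(vals)
        best <- pp[which.max(vals), ]
      }
    }
    map <- as.integer(best)
  } else {
    map <- integer(n1)
    avail <- rep(TRUE, n2)
    for (i in order(apply(sim, 1, max), decreasing = TRUE)) {
      j <- which(avail)[which.max(sim[i, avail])]
      map[i] <- j
      avail[j] <- FALSE
    }
  }
  list(map = map, transposed = transposed)
}

#' Match features between two fits
#'
#' Pairs features from two fits one-to-one so as to maximize the total
#' cosine similarity of their weight vectors (or any row-wise feature
#' representation, e.g. profile vectors). Feature identity is not meaningful
#' across sampler runs (label switching), so all cross-run comparisons go
#' through this matching.
#'
#' @param a1,a2 Matrices whose rows are feature representations (K1 x D and
#'   K2 x D).
#' @return A data frame of class `feature_match_result`: `feature_1`,
#'   `feature_2` (row indices into `a1`, `a2`), `similarity`.
#' @export
match_features <- function(a1, a2) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  sim <- cosine_similarity_matrix(a1, a2)
  res <- assign_one_to_one(sim)
  if (length(res$map) == 0) {
    out <- data.frame(feature_1 = integer(0), feature_2 = integer(0),
                      similarity = numeric(0))
  } else if (res$transposed) {
    out <- data.frame(feature_1 = res$map,
                      feature_2 = seq_along(res$map),
                      similarity = sim[cbind(res$map, seq_along(res$map))])
  } else {
    out <- data.frame(feature_1 = seq_along(res$map), feature_2 = res$map,
                      similarity = sim[cbind(seq_along(res$map), res$map)])
  }
  class(out) <- c("feature_match_result", "data.frame")
  out
}

#' Split-half stability of the latent features
#'
#' Randomly halves the participants (seeded), fits the sampler on each half,
#' filters features within each half at `fraction` of the half's size, and
#' matches the retained features across halves by maximal total cosine
#' similarity of their weight vectors. A half with zero retained features
#' yields an empty match table (reported, not an error).
#'
#' @param battery Battery (or matrix) to fit.
#' @param sweeps,hypers,k_cap Sampler settings passed to [run_ibp()].
#' @param fraction Retention fraction per half. Default 0.05.
#' @param seed Integer seed controlling the split and both fits.
#' @return A list of class `split_half_result`: `match` (a
#'   [match_features()] table over retained features), `halves` (row
#'   indices), `filters` (per-half [filter_features()] results).
#' @export
split_half_stability <- function(battery, sweeps = 50, hypers = NULL,
                                 k_cap = 4, fraction = 0.05, seed = 1L) {
  md <- as_model_data(battery)
  n <- md$n
  if (n < 4) stop("need at least 4 participants to split", call. = FALSE)
  set.seed(seed)
  first <- sort(sample.int(n, floor(n / 2)))
  halves <- list(first = first, second = setdiff(seq_len(n), first))
  fits <- lapply(seq_along(halves), function(h) {
    idx <- halves[[h]]
    run_ibp(md$xv[idx, , drop = FALSE] +
              ifelse(md$mask[idx, , drop = FALSE], 0, NA),
            sweeps = sweeps, seed = seed + h, hypers = hypers, k_cap = k_cap)
  })
  filters <- lapply(seq_along(fits), function(h) {
    filter_features(fits[[h]]$state$z,
                    inclusion_threshold(length(halves[[h]]), fraction))
  })
  a1 <- fits[[1]]$state$a[filters[[1]]$retained, , drop = FALSE]
  a2 <- fits[[2]]$state$a[filters[[2]]$retained, , drop = FALSE]
  match <- if (nrow(a1) == 0 || nrow(a2) == 0) {
    structure(data.frame(feature_1 = integer(0), feature_2 = integer(0),
                         similarity = numeric(0)),
              class = c("feature_match_result", "data.frame"))
  } else {
    m <- match_features(a1, a2)
    m$feature_1 <- filters[[1]]$retained[m$feature_1]
    m$feature_2 <- filters[[2]]$retained[m$feature_2]
    m
  }
  structure(list(match = match, halves = halves, filters = filters,
                 fits = fits, seed = seed),
            class = "split_half_result")
}

#' @export
print.split_half_result <- function(x, ...) {
  cat(sprintf("<split_half_result> %d matched feature pair(s)\n",
              nrow(x$match)))
  if (nrow(x$match) > 0) {
    cat("  similarities:",
        paste(sprintf("%.3f", x$match$similarity), collapse = ", "), "\n")
  }
  invisible(x)
}
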