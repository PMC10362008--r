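# Shared fixtures and independent oracles used across the suite.

# a tiny schema with d generic measures (one optionally reverse scored)
tiny_schema <- function(d = 3, reverse = integer(0)) {
  measure_schema(data.frame(
    measure_id = paste0("m", seq_len(d)),
    battery = "CNB",
    subfunction = "test",
    score_label = "score",
    higher_is_better_raw = TRUE,
    reverse_score = seq_len(d) %in% reverse,
    stringsAsFactors = FALSE))
}

tiny_battery <- function(values, reverse = integer(0)) {
  values <- as.matrix(values)
  raw_battery(values, paste0("p", seq_len(nrow(values))),
              tiny_schema(ncol(values), reverse))
}

# independent re-derivation of the Steiger (1980) overlapping-correlation z,
# written from the published formula without reference to the package code
oracle_steiger_z <- function(r1, r2, r12, n) {
  z1 <- 0.5 * log((1 + r1) / (1 - r1))
  z2 <- 0.5 * log((1 + r2) / (1 - r2))
  rm2 <- ((r1 + r2) / 2)^2
  c_num <- r12 * (1 - 2 * rm2) - 0.5 * rm2 * (1 - 2 * rm2 - r12^2)
  c_val <- c_num / (1 - rm2)^2
  (z1 - z2) * sqrt((n - 3) / (2 - 2 * c_val))
}

# draw n rows from a trivariate normal with unit variances and the given
# correlations (j, k, y ordering); cholesky by hand so the oracle does not
# depend on the package
rtrivariate <- function(n, r_jk, r_jy, r_ky) {
  sig <- matrix(c(1, r_jk, r_jy,
                  r_jk, 1, r_ky,
                  r_jy, r_ky, 1), 3, 3)
  matrix(stats::rnorm(3 * n), n, 3) %*% chol(sig)
}

# exhaustive posterior over K for a complete-data linear-Gaussian IBP on a
# tiny instance: sums IBP prior x collapsed marginal over all ordered tuples
# of <= max_k nonzero binary columns (ordered tuples weighted by
# alpha^K / K! reproduce the left-ordered equivalence-class prior)
enumerate_posterior_k <- function(x, alpha, sigma_x, sigma_a, max_k = 3) {
  n <- nrow(x)
  cols <- as.matrix(expand.grid(rep(list(0:1), n)))[-1, , drop = FALSE]
  lw_col <- function(m) lgamma(n - m + 1) + lgamma(m) - lgamma(n + 1)
  post <- numeric(max_k + 1)
  post[1] <- exp(collapsed_log_marginal(x, matrix(0, n, 0),
                                        sigma_x, sigma_a))
  for (k in seq_len(max_k)) {
    idx <- as.matrix(expand.grid(rep(list(seq_len(nrow(cols))), k)))
    tot <- 0
    for (r in seq_len(nrow(idx))) {
      z <- t(cols[idx[r, ], , drop = FALSE])
      lp <- k * log(alpha) - lgamma(k + 1) + sum(lw_col(colSums(z))) +
        collapsed_log_marginal(x, z, sigma_x, sigma_a)
      tot <- tot + exp(lp)
    }
    post[k + 1] <- tot
  }
  post / sum(post)
}
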