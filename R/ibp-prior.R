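#' Hyperparameters for the linear-Gaussian IBP sampler
#'
#' `alpha` is the IBP concentration (expected number of features is
#' `alpha * H_N`, with `H_N` the N-th harmonic number); `sigma_x` and
#' `sigma_a` are the observation-noise and weight-prior standard deviations.
#' `alpha` carries a conjugate Gamma(shape, rate) prior; the noise scales are
#' updated by random-walk Metropolis on the log scale with proposal SD
#' `sigma_proposal_scale` under a Jeffreys (flat-on-log) prior.
#'
#' @param alpha Positive concentration parameter. Default 5 (the
#'   initialization used for the neurocognitive battery analysis).
#' @param sigma_x Positive observation-noise SD. Default 1.
#' @param sigma_a Positive weight-prior SD. Default 1.
#' @param alpha_prior_shape,alpha_prior_rate Positive Gamma prior parameters
#'   for `alpha`. Defaults 1, 1.
#' @param sigma_proposal_scale Positive SD of the log-scale random-walk
#'   proposal for `sigma_x` and `sigma_a` (used when
#'   `scale_update = "metropolis"`). Default 0.1.
#' @param scale_update How the sampler refreshes the noise scales each
#'   sweep: `"conjugate"` (default; exact inverse-gamma draws given the
#'   weights and residuals, so the scales adapt in one step) or
#'   `"metropolis"` (one log-scale random-walk step each).
#' @return A list of class `ibp_hyperparameters`.
#' @export
ibp_hyperparameters <- function(alpha = 5, sigma_x = 1, sigma_a = 1,
                                alpha_prior_shape = 1, alpha_prior_rate = 1,
                                sigma_proposal_scale = 0.1,
                                scale_update = c("conjugate", "metropolis")) {
  scale_update <- match.arg(scale_update)
  h <- list(alpha = alpha, sigma_x = sigma_x, sigma_a = sigma_a,
            alpha_prior_shape = alpha_prior_shape,
            alpha_prior_rate = alpha_prior_rate,
            sigma_proposal_scale = sigma_proposal_scale)
  bad <- names(h)[!vapply(h, function(v) is.numeric(v) && length(v) == 1 &&
                            is.finite(v) && v > 0, logical(1))]
  # the proposal scale may be exactly 0 (degenerate proposal leaves scales fixed)
  bad <- setdiff(bad, if (identical(h$sigma_proposal_scale, 0)) "sigma_proposal_scale")
  if (length(bad) > 0) {
    stop("hyperparameters must be strictly positive scalars: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  h$scale_update <- scale_update
  structure(h, class = "ibp_hyperparameters")
}

#' Harmonic number
#' @param n Positive integer.
#' @return `sum(1 / (1:n))`.
#' @keywords internal
harmonic_number <- function(n) sum(1 / seq_len(n))

#' Simulate a binary feature matrix from the IBP prior
#'
#' Sequential "buffet" construction: customer 1 samples `Poisson(alpha)` new
#' dishes (columns); each subsequent customer `i` samples existing dish `k`
#' with probability `m_k / i` (`m_k` = number of previous customers who
#' sampled it) and `Poisson(alpha / i)` new dishes.
#'
#' @param n Number of rows (customers). `n >= 1`.
#' @param alpha Nonnegative concentration parameter.
#' @param seed Optional integer seed for reproducibility.
#' @return An `n x K` binary matrix (`K` may be 0).
#' @export
ibp_prior_draw <- function(n, alpha, seed = NULL) {
  stopifnot(n >= 1, alpha >= 0)
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(0L, nrow = n, ncol = 0)
  for (i in seq_len(n)) {
    k <- ncol(z)
    if (k > 0) {
      m <- colSums(z[seq_len(i - 1L), , drop = FALSE])
      z[i, ] <- as.integer(stats::runif(k) < m / i)
    }
    k_new <- stats::rpois(1, alpha / i)
    if (k_new > 0) {
      add <- matrix(0L, nrow = n, ncol = k_new)
      add[i, ] <- 1L
      z <- cbind(z, add)
    }
  }
  z
}

#' Log prior density of a binary feature matrix under the IBP
#'
#' Evaluates the exchangeable IBP prior over equivalence classes of
#' column-orderings (left-ordered form):
#' `log P = K log(alpha) - alpha * H_N - sum_h log(K_h!) +
#'  sum_k log((N - m_k)! (m_k - 1)! / N!)`,
#' where `K_h` counts columns sharing an identical binary pattern.
#'
#' @param z Binary matrix with no all-zero columns.
#' @param alpha Positive concentration.
#' @return Log prior density (scalar).
#' @export
ibp_log_prior <- function(z, alpha) {
  n <- nrow(z)
  k <- ncol(z)
  if (k == 0) return(-alpha * harmonic_number(n))
  m <- colSums(z)
  if (any(m == 0)) stop("z has an all-zero column", call. = FALSE)
  patterns <- apply(z, 2, paste, collapse = "")
  kh <- table(patterns)
  k * log(alpha) - alpha * harmonic_number(n) - sum(lgamma(kh + 1)) +
    sum(lgamma(n - m + 1) + lgamma(m) - lgamma(n + 1))
}

#' Conjugate Gamma update for the IBP concentration parameter
#'
#' Given `k_plus` retained features among `n` rows, draws
#' `alpha ~ Gamma(shape + k_plus, rate + H_n)` — the conjugate posterior for
#' the IBP feature count.
#'
#' @param k_plus Nonnegative integer count of retained features.
#' @param n Number of rows.
#' @param shape,rate Positive Gamma prior parameters.
#' @return A single positive draw.
#' @export
resample_alpha <- function(k_plus, n, shape = 1, rate = 1) {
  stopifnot(k_plus >= 0, n >= 1, shape > 0, rate > 0)
  stats::rgamma(1, shape = shape + k_plus, rate = rate + harmonic_number(n))
}
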