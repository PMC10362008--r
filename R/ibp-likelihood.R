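#' Collapsed log marginal likelihood of the linear-Gaussian model
#'
#' Evaluates `log p(X | Z, sigma_x, sigma_a)` for the model
#' `X = Z A + E`, `A[k, d] ~ N(0, sigma_a^2)`, `E[i, d] ~ N(0, sigma_x^2)`,
#' with the weights integrated out analytically:
#' \deqn{-\frac{1}{2\sigma_X^2}\mathrm{tr}(X^\top(I - Z M Z^\top)X)
#'   - \frac{ND}{2}\log(2\pi) - (N-K)D\log\sigma_X - KD\log\sigma_A
#'   - \frac{D}{2}\log|Z^\top Z + (\sigma_X^2/\sigma_A^2) I|,}
#' with `M = (Z'Z + (sigma_x^2/sigma_a^2) I)^{-1}`. Complete data only: this
#' path is used by enumeration oracles; per-cell missingness is handled by
#' the uncollapsed sampler ([run_ibp()]).
#'
#' @param x Numeric N x D matrix (or a battery object) with no missing cells.
#' @param z Binary N x K matrix (K may be 0).
#' @param sigma_x,sigma_a Positive noise and weight-prior SDs.
#' @return Scalar log marginal likelihood.
#' @export
collapsed_log_marginal <- function(x, z, sigma_x, sigma_a) {
  if (inherits(x, "ncog_battery")) {
    if (!all(x$mask)) {
      stop("collapsed_log_marginal supports complete data only; ",
           "use the uncollapsed sampler (run_ibp) for masked cells",
           call. = FALSE)
    }
    x <- x$values
  }
  x <- as.matrix(x)
  if (anyNA(x)) {
    stop("collapsed_log_marginal supports complete data only; ",
         "use the uncollapsed sampler (run_ibp) for masked cells",
         call. = FALSE)
  }
  z <- as.matrix(z)
  n <- nrow(x); d <- ncol(x); k <- ncol(z)
  if (k == 0) {
    return(sum(stats::dnorm(x, 0, sigma_x, log = TRUE)))
  }
  stopifnot(nrow(z) == n)
  ratio <- sigma_x^2 / sigma_a^2
  g <- crossprod(z) + diag(ratio, k)
  ch <- chol(g)
  logdet <- 2 * sum(log(diag(ch)))
  zx <- crossprod(z, x)                      # K x D
  # tr(X'(I - Z M Z')X) = tr(X'X) - tr((Z'X)' M (Z'X))
  v <- backsolve(ch, zx, transpose = TRUE)   # solves t(ch) v = zx
  quad <- sum(x^2) - sum(v^2)
  -quad / (2 * sigma_x^2) - (n * d / 2) * log(2 * pi) -
    (n - k) * d * log(sigma_x) - k * d * log(sigma_a) - (d / 2) * logdet
}

# log-likelihood of one row's unmasked cells given its residual vector
row_loglik <- function(resid, obs, sigma_x) {
  sum(stats::dnorm(resid[obs], 0, sigma_x, log = TRUE))
}

# Gaussian full-conditional of weight column d (length-K vector) given Z,
# restricted to rows with an unmasked cell in measure d.
# Returns list(mean, chol_precision); with no unmasked rows the posterior is
# the prior.
weight_posterior <- function(z, x_d, obs_d, sigma_x, sigma_a) {
  k <- ncol(z)
  if (!any(obs_d)) {
    return(list(mean = rep(0, k), chol_prec = diag(1 / sigma_a, k)))
  }
  zd <- z[obs_d, , drop = FALSE]
  prec <- crossprod(zd) / sigma_x^2 + diag(1 / sigma_a^2, k)
  ch <- chol(prec)
  b <- crossprod(zd, x_d[obs_d]) / sigma_x^2
  mu <- backsolve(ch, backsolve(ch, b, transpose = TRUE))
  list(mean = drop(mu), chol_prec = ch)
}
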