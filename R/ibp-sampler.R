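# Uncollapsed Gibbs sampler for the linear-Gaussian IBP with per-cell
# missingness. The binary matrix Z is updated row-wise with explicit weights
# A; new singleton features are proposed with their weights integrated
# against the prior (a valid blocked update); A, alpha and the noise scales
# are refreshed once per sweep.

# normalize input to list(xv, mask, n, d): xv holds 0 at masked cells so
# matrix products never propagate NA; mask is TRUE where observed.
as_model_data <- function(x, mask = NULL) {
  if (inherits(x, "ncog_battery")) {
    mask <- x$mask
    x <- x$values
  }
  x <- as.matrix(x)
  if (is.null(mask)) mask <- !is.na(x)
  x[!mask] <- 0
  list(xv = x, mask = mask, n = nrow(x), d = ncol(x))
}

#' Sampler state for the linear-Gaussian IBP
#'
#' Bundles the binary feature matrix `z` (N x K), the weight matrix `a`
#' (K x D), the current hyperparameter values, and bookkeeping (iteration
#' counter, seed, stable per-column ids used to track feature identity
#' across sweeps).
#'
#' @param z Binary N x K matrix.
#' @param a Numeric K x D matrix.
#' @param hypers An [ibp_hyperparameters()] object giving current `alpha`,
#'   `sigma_x`, `sigma_a` and update settings.
#' @param iteration Nonnegative integer sweep counter.
#' @param seed Integer seed recorded for provenance.
#' @return An object of class `ibp_state`.
#' @export
ibp_state <- function(z, a, hypers = ibp_hyperparameters(),
                      iteration = 0L, seed = NA_integer_) {
  z <- as.matrix(z); a <- as.matrix(a)
  if (ncol(z) != nrow(a)) {
    stop("z has ", ncol(z), " columns but a has ", nrow(a), " rows",
         call. = FALSE)
  }
  if (!all(z %in% c(0, 1))) stop("z must be binary", call. = FALSE)
  structure(list(z = z, a = a, alpha = hypers$alpha,
                 sigma_x = hypers$sigma_x, sigma_a = hypers$sigma_a,
                 hypers = hypers, iteration = as.integer(iteration),
                 seed = seed, col_ids = seq_len(ncol(z)),
                 next_id = ncol(z) + 1L),
            class = "ibp_state")
}

#' @export
print.ibp_state <- function(x, ...) {
  cat(sprintf(paste0("<ibp_state> iteration %d: K = %d features, ",
                     "alpha = %.3f, sigma_x = %.3f, sigma_a = %.3f\n"),
              x$iteration, ncol(x$z), x$alpha, x$sigma_x, x$sigma_a))
  invisible(x)
}

#' Full-conditional inclusion probability for an existing feature
#'
#' Returns `P(z[i, k] = 1 | rest) = (m/N) L1 / ((m/N) L1 + (1 - m/N) L0)`,
#' where `m` is feature `k`'s popularity excluding row `i` and `L1`, `L0`
#' are the likelihoods of row `i`'s unmasked cells under the current weights
#' with `z[i, k]` set to 1 or 0. A fully masked row contributes no
#' likelihood, so the probability reduces to the prior `m / N`.
#'
#' @param state An [ibp_state()].
#' @param x Battery or numeric matrix (NA = masked).
#' @param i Row index.
#' @param k Feature (column) index; its popularity excluding `i` must be
#'   at least 1 (empty or row-`i`-singleton columns belong to the
#'   new-feature step).
#' @return Probability in \[0, 1\].
#' @export
conditional_inclusion_probability <- function(state, x, i, k) {
  md <- as_model_data(x)
  z <- state$z; a <- state$a
  n <- md$n
  m <- sum(z[, k]) - z[i, k]
  if (m < 1) {
    stop("feature ", k, " has popularity 0 excluding row ", i,
         "; it is handled by the new-feature step", call. = FALSE)
  }
  mi <- md$mask[i, ]
  r <- md$xv[i, ] - drop(z[i, ] %*% a)
  r0 <- if (z[i, k] == 1) r + a[k, ] else r
  r1 <- r0 - a[k, ]
  dll <- sum(r0[mi]^2 - r1[mi]^2) / (2 * state$sigma_x^2)
  1 / (1 + ((n - m) / m) * exp(-dll))
}

# sample the number of new singleton features for row i and draw their
# weights from the exact posterior given row i's unmasked data. `r` is the
# row residual, `mi` the row mask. Returns list(j, a_new, r).
draw_new_singletons <- function(r, mi, alpha, n, d, sigma_x, sigma_a, cap) {
  if (cap < 1 || alpha <= 0) return(list(j = 0L, a_new = NULL, r = r))
  js <- 0:cap
  robs <- r[mi]
  nobs <- length(robs)
  ss <- sum(robs^2)
  vars <- sigma_x^2 + js * sigma_a^2
  logw <- stats::dpois(js, alpha / n, log = TRUE) -
    0.5 * nobs * log(2 * pi * vars) - ss / (2 * vars)
  logw <- logw - max(logw)
  j <- sample(js, 1, prob = exp(logw))
  if (j == 0) return(list(j = 0L, a_new = NULL, r = r))
  # posterior for the j new weights in measure d (unmasked): precision
  # (1/sx^2) J + (1/sa^2) I, mean solve(prec, 1) * r_d / sx^2 -- shared
  # across measures. Masked measures draw from the prior.
  prec <- matrix(1 / sigma_x^2, j, j) + diag(1 / sigma_a^2, j)
  ch <- chol(prec)
  u <- backsolve(ch, backsolve(ch, rep(1, j), transpose = TRUE)) / sigma_x^2
  a_new <- backsolve(ch, matrix(stats::rnorm(j * d), j, d))
  a_new <- a_new + drop(u) %o% (r * mi)
  if (any(!mi)) {
    nmiss <- sum(!mi)
    a_new[, !mi] <- matrix(stats::rnorm(j * nmiss, 0, sigma_a), j, nmiss)
  }
  list(j = as.integer(j), a_new = a_new, r = r - colSums(a_new))
}

#' Propose new singleton features for one row
#'
#' Samples the number of new features sampled only by row `i` from the
#' truncated conditional over `0..k_cap` (prior `Poisson(alpha / N)` per
#' count, likelihood of row `i`'s unmasked residuals with the new weights
#' integrated against their `N(0, sigma_a^2)` prior), then draws weights for
#' the accepted columns from their exact posterior given row `i`'s data.
#' Row `i`'s existing singleton columns should have been removed first (the
#' sweep drops them during the existing-feature update).
#'
#' @param state An [ibp_state()].
#' @param x Battery or numeric matrix (NA = masked).
#' @param i Row index.
#' @param k_cap Maximum number of new features per proposal. Default 4.
#' @param max_k Optional cap on the total feature count (Inf = unbounded).
#' @return An updated [ibp_state()].
#' @export
propose_new_features <- function(state, x, i, k_cap = 4, max_k = Inf) {
  md <- as_model_data(x)
  cap <- min(k_cap, max_k - ncol(state$z))
  r <- md$xv[i, ] - drop(state$z[i, ] %*% state$a)
  res <- draw_new_singletons(r, md$mask[i, ], state$alpha, md$n, md$d,
                             state$sigma_x, state$sigma_a, cap)
  if (res$j > 0) {
    add <- matrix(0, md$n, res$j)
    add[i, ] <- 1
    state$z <- cbind(state$z, add)
    state$a <- rbind(state$a, res$a_new)
    state$col_ids <- c(state$col_ids,
                       seq(state$next_id, length.out = res$j))
    state$next_id <- state$next_id + res$j
  }
  state
}

# draw A from its full conditional given Z, using for each measure d only
# the rows with an unmasked cell in d (prior fallback when none).
sample_weights_engine <- function(z, md, sigma_x, sigma_a) {
  k <- ncol(z)
  d <- md$d
  a <- matrix(0, k, d)
  for (jd in seq_len(d)) {
    obs <- md$mask[, jd]
    wp <- weight_posterior(z, md$xv[, jd], obs, sigma_x, sigma_a)
    a[, jd] <- wp$mean + backsolve(wp$chol_prec, stats::rnorm(k))
  }
  a
}

#' Draw the weight matrix from its full conditional
#'
#' Samples `A` column-by-column (one Gaussian full conditional per measure),
#' using for measure `d` only the rows whose cell `(i, d)` is unmasked:
#' posterior precision `Z_d' Z_d / sigma_x^2 + I / sigma_a^2`, posterior mean
#' `precision^{-1} Z_d' x_d / sigma_x^2`. A measure with no unmasked rows
#' draws its weight column from the `N(0, sigma_a^2)` prior.
#'
#' @param state An [ibp_state()] with at least one feature.
#' @param x Battery or numeric matrix (NA = masked).
#' @return A K x D weight matrix.
#' @export
sample_weights <- function(state, x) {
  stopifnot(ncol(state$z) >= 1)
  md <- as_model_data(x)
  sample_weights_engine(state$z, md, state$sigma_x, state$sigma_a)
}

# one log-scale random-walk Metropolis update of a scale parameter.
# loglik_fn(sigma) must return the log density of the data given sigma;
# the prior is Jeffreys (flat on log sigma), so the acceptance ratio is the
# likelihood ratio alone.
mh_scale_update <- function(sigma, proposal_sd, loglik_fn) {
  if (proposal_sd <= 0) return(sigma)
  prop <- exp(log(sigma) + stats::rnorm(1, 0, proposal_sd))
  if (log(stats::runif(1)) < loglik_fn(prop) - loglik_fn(sigma)) prop else sigma
}

# conjugate (inverse-gamma under the Jeffreys 1/sigma^2 prior) draws of the
# noise scales given Z, A: sigma_x^2 ~ SS_resid / chisq(n_obs),
# sigma_a^2 ~ SS_weights / chisq(K * D). Exact Gibbs, so the scales adapt in
# one step instead of random-walking.
conjugate_scale_update <- function(state, md) {
  resid <- md$xv - state$z %*% state$a
  robs <- resid[md$mask]
  sigma_x <- sqrt(sum(robs^2) / stats::rchisq(1, df = length(robs)))
  sigma_a <- state$sigma_a
  if (length(state$a) > 0) {
    sigma_a <- sqrt(sum(state$a^2) / stats::rchisq(1, df = length(state$a)))
  }
  c(sigma_x = sigma_x, sigma_a = sigma_a)
}

resample_noise_scales_engine <- function(state, md) {
  ps <- state$hypers$sigma_proposal_scale
  resid <- md$xv - state$z %*% state$a
  robs <- resid[md$mask]
  ss_x <- sum(robs^2)
  n_obs <- length(robs)
  sigma_x <- mh_scale_update(state$sigma_x, ps, function(s) {
    -n_obs * log(s) - ss_x / (2 * s^2)
  })
  sigma_a <- state$sigma_a
  if (length(state$a) > 0) {
    ss_a <- sum(state$a^2)
    n_a <- length(state$a)
    sigma_a <- mh_scale_update(sigma_a, ps, function(s) {
      -n_a * log(s) - ss_a / (2 * s^2)
    })
  }
  c(sigma_x = sigma_x, sigma_a = sigma_a)
}

#' Metropolis update of the noise scales
#'
#' Updates `sigma_x` (via the Gaussian density of the unmasked residuals
#' `X - Z A`) and `sigma_a` (via the Gaussian density of the weights) by one
#' random-walk Metropolis step each on the log scale, with proposal SD
#' `sigma_proposal_scale` and a Jeffreys prior (flat on the log scale).
#' With no features, `sigma_a` has no likelihood and is left unchanged.
#'
#' @param state An [ibp_state()].
#' @param x Battery or numeric matrix (NA = masked).
#' @return Named numeric vector `c(sigma_x = ..., sigma_a = ...)`.
#' @export
resample_noise_scales <- function(state, x) {
  resample_noise_scales_engine(state, as_model_data(x))
}

# weight-collapsed ("accelerated") sweep over all rows: flips of existing
# features and the singleton-count redraws evaluate the marginal likelihood
# of each row's unmasked cells with the weights integrated out. With missing
# data the collapsed marginal factorizes over measures (each measure's
# weight column has its own Gaussian posterior from the rows observed in
# that measure), so per-cell missingness is handled exactly. Sufficient
# statistics G_d = Z_d' Z_d (stored as a K^2 x D matrix) and B = Z' X are
# maintained by rank-1 updates and rebuilt when K changes.
accelerated_sweep <- function(state, md, k_cap, max_k) {
  z <- state$z
  col_ids <- state$col_ids
  next_id <- state$next_id
  alpha <- state$alpha
  sx2 <- state$sigma_x^2
  sa2 <- state$sigma_a^2
  n <- md$n
  d_tot <- md$d
  xv <- md$xv
  mask <- md$mask
  cs <- if (ncol(z) > 0) colSums(z) else numeric(0)

  rebuild <- function() {
    k <- ncol(z)
    if (k == 0) {
      list(g = matrix(0, 0, d_tot), b = matrix(0, 0, d_tot))
    } else {
      g <- matrix(0, k * k, d_tot)
      for (d in seq_len(d_tot)) {
        g[, d] <- crossprod(z, z * mask[, d])
      }
      list(g = g, b = crossprod(z, xv))  # xv is 0 at masked cells
    }
  }
  st <- rebuild()

  for (i in seq_len(n)) {
    obs <- which(mask[i, ])
    nobs <- length(obs)
    k <- ncol(z)
    zi <- if (k > 0) z[i, ] else numeric(0)
    zi_old <- zi
    cs_minus <- cs - zi
    sing <- cs_minus == 0 & zi == 1
    empty <- cs_minus == 0 & zi == 0
    idx <- which(!sing & !empty)
    ks <- length(idx)
    ns_old <- sum(sing)
    xrow <- xv[i, obs]
    if (ks > 0) {
      zis <- zi[idx]
      mu <- matrix(0, ks, nobs)
      sarr <- array(0, c(ks, ks, nobs))
      sz <- matrix(0, ks, nobs)
      m0 <- numeric(nobs)
      v0 <- numeric(nobs)
      zz <- zi[idx] %o% zi[idx]
      for (jd in seq_len(nobs)) {
        d <- obs[jd]
        gsub <- matrix(st$g[, d], k, k)[idx, idx] - zz
        p <- gsub / sx2 + diag(1 / sa2, ks)
        s <- chol2inv(chol(p))
        mu[, jd] <- s %*% ((st$b[idx, d] - zi[idx] * xrow[jd]) / sx2)
        sarr[, , jd] <- s
        sz[, jd] <- s %*% zis
        m0[jd] <- sum(zis * mu[, jd])
        v0[jd] <- sum(zis * sz[, jd]) + sx2
      }
      # row-i singletons have no other members: their weights are
      # integrated against the prior, adding ns_old * sa^2 variance
      v0 <- v0 + ns_old * sa2
      for (kk in seq_len(ks)) {
        m <- cs_minus[idx[kk]]
        sgn <- if (zis[kk] == 1) -1 else 1
        m1 <- m0 + sgn * mu[kk, ]
        v1 <- v0 + 2 * sgn * sz[kk, ] + sarr[kk, kk, ]
        dll <- sum(stats::dnorm(xrow, m1, sqrt(v1), log = TRUE) -
                     stats::dnorm(xrow, m0, sqrt(v0), log = TRUE))
        dll10 <- if (zis[kk] == 1) -dll else dll  # log L1 - log L0
        p1 <- 1 / (1 + ((n - m) / m) * exp(-dll10))
        new1 <- stats::runif(1) < p1
        if (new1 != (zis[kk] == 1)) {
          m0 <- m1
          v0 <- v1
          sz <- sz + sgn * matrix(sarr[, kk, ], nrow = ks)
          cs[idx[kk]] <- cs[idx[kk]] + sgn
          zis[kk] <- 1 - zis[kk]
        }
      }
      zi[idx] <- zis
      z[i, ] <- zi
    } else {
      m0 <- rep(0, nobs)
      v0 <- rep(sx2 + ns_old * sa2, nobs)
    }
    # blocked redraw of the singleton count: remove the row's singletons
    # and sample j from Poisson(alpha / N) x marginal likelihood with j new
    # integrated weight rows (each adds sa^2 predictive variance)
    vbase <- v0 - ns_old * sa2
    structural <- any(sing) || any(empty)
    if (structural) {
      keep <- !(sing | empty)
      z <- z[, keep, drop = FALSE]
      cs <- cs[keep]
      col_ids <- col_ids[keep]
      zi <- zi[keep]
      zi_old <- zi_old[keep]
    }
    cap <- min(k_cap, max_k - ncol(z))
    j <- 0L
    if (cap >= 1 && alpha > 0) {
      js <- 0:cap
      lw <- stats::dpois(js, alpha / n, log = TRUE) +
        vapply(js, function(jj) {
          sum(stats::dnorm(xrow, m0, sqrt(vbase + jj * sa2), log = TRUE))
        }, numeric(1))
      lw <- lw - max(lw)
      j <- sample(js, 1, prob = exp(lw))
    }
    if (j > 0) {
      add <- matrix(0, n, j)
      add[i, ] <- 1
      z <- cbind(z, add)
      cs <- c(cs, rep(1, j))
      col_ids <- c(col_ids, seq(next_id, length.out = j))
      next_id <- next_id + as.integer(j)
    }
    if (structural || j > 0) {
      st <- rebuild()
    } else if (ncol(z) > 0 && any(zi != zi_old)) {
      delta <- as.vector(zi %o% zi - zi_old %o% zi_old)
      st$g[, obs] <- st$g[, obs] + delta
      st$b[, obs] <- st$b[, obs] + (zi - zi_old) %o% xrow
    }
  }
  state$z <- z
  state$col_ids <- col_ids
  state$next_id <- next_id
  state
}

# one full sweep over the data; operates on plain components for speed.
# Returns the updated state with a $last_record field.
gibbs_sweep_engine <- function(state, md, k_cap, max_k,
                               update_alpha, update_scales,
                               method = "accelerated") {
  if (method == "accelerated") {
    state <- accelerated_sweep(state, md, k_cap, max_k)
    return(finish_sweep(state, md, update_alpha, update_scales))
  }
  z <- state$z; a <- state$a
  alpha <- state$alpha; sx <- state$sigma_x; sa <- state$sigma_a
  hyp <- state$hypers
  col_ids <- state$col_ids
  next_id <- state$next_id
  n <- md$n; d <- md$d
  xv <- md$xv; mask <- md$mask
  cs <- if (ncol(z) > 0) colSums(z) else numeric(0)
  two_sx2 <- 2 * sx^2

  for (i in seq_len(n)) {
    k <- ncol(z)
    mi <- mask[i, ]
    if (k > 0) {
      zi <- z[i, ]
      r <- xv[i, ] - drop(zi %*% a)
      drop_cols <- rep(FALSE, k)
      for (kk in seq_len(k)) {
        m <- cs[kk] - zi[kk]
        if (m < 1) {
          # popularity excluding i is 0. A row-i singleton is NOT flipped
          # here: it stays in place (its weights keep explaining the row)
          # and is removed atomically with the new-feature redraw below, so
          # that removal + redraw form one blocked update of the row's
          # singleton set. A column that is empty outright is dropped.
          drop_cols[kk] <- zi[kk] == 0
          next
        }
        r0 <- if (zi[kk] == 1) r + a[kk, ] else r
        r1 <- r0 - a[kk, ]
        dll <- sum(r0[mi]^2 - r1[mi]^2) / two_sx2
        p1 <- 1 / (1 + ((n - m) / m) * exp(-dll))
        if (stats::runif(1) < p1) {
          if (zi[kk] == 0) cs[kk] <- cs[kk] + 1
          zi[kk] <- 1
          r <- r1
        } else {
          if (zi[kk] == 1) cs[kk] <- cs[kk] - 1
          zi[kk] <- 0
          r <- r0
        }
      }
      # remove the row's singleton columns now (the atomic first half of the
      # blocked singleton-count update; the redraw follows immediately)
      singles <- cs - zi == 0 & zi == 1
      if (any(singles)) {
        r <- r + colSums(a[singles, , drop = FALSE])
        zi[singles] <- 0
        cs[singles] <- 0
        drop_cols <- drop_cols | singles
      }
      z[i, ] <- zi
      if (any(drop_cols)) {
        keep <- !drop_cols
        z <- z[, keep, drop = FALSE]
        a <- a[keep, , drop = FALSE]
        cs <- cs[keep]
        col_ids <- col_ids[keep]
      }
    } else {
      r <- xv[i, ]
    }
    cap <- min(k_cap, max_k - ncol(z))
    res <- draw_new_singletons(r, mi, alpha, n, d, sx, sa, cap)
    if (res$j > 0) {
      add <- matrix(0, n, res$j)
      add[i, ] <- 1
      z <- cbind(z, add)
      a <- rbind(a, res$a_new)
      cs <- c(cs, rep(1, res$j))
      col_ids <- c(col_ids, seq(next_id, length.out = res$j))
      next_id <- next_id + res$j
    }
  }

  state$z <- z
  state$a <- a
  state$col_ids <- col_ids
  state$next_id <- next_id
  finish_sweep(state, md, update_alpha, update_scales)
}

# shared end-of-sweep stage: prune empty columns, redraw the weights from
# their full conditional, resample alpha (conjugate) and the noise scales
# (Metropolis), increment the iteration, and attach the trace record.
finish_sweep <- function(state, md, update_alpha, update_scales) {
  hyp <- state$hypers
  if (ncol(state$z) > 0) {
    keep <- colSums(state$z) > 0
    if (!all(keep)) {
      state$z <- state$z[, keep, drop = FALSE]
      state$col_ids <- state$col_ids[keep]
      if (nrow(state$a) == length(keep)) {
        state$a <- state$a[keep, , drop = FALSE]
      }
    }
  }
  if (ncol(state$z) > 0) {
    state$a <- sample_weights_engine(state$z, md, state$sigma_x,
                                     state$sigma_a)
  } else {
    state$a <- matrix(0, 0, md$d)
  }
  if (update_alpha) {
    state$alpha <- resample_alpha(ncol(state$z), md$n,
                                  hyp$alpha_prior_shape,
                                  hyp$alpha_prior_rate)
  }
  if (update_scales) {
    sc <- if (identical(state$hypers$scale_update, "metropolis")) {
      resample_noise_scales_engine(state, md)
    } else {
      conjugate_scale_update(state, md)
    }
    state$sigma_x <- sc[["sigma_x"]]
    state$sigma_a <- sc[["sigma_a"]]
  }
  state$iteration <- state$iteration + 1L
  resid <- md$xv - state$z %*% state$a
  log_joint <- sum(stats::dnorm(resid[md$mask], 0, state$sigma_x,
                                log = TRUE)) +
    sum(stats::dnorm(state$a, 0, state$sigma_a, log = TRUE)) +
    ibp_log_prior(state$z, state$alpha)
  state$last_record <- c(iteration = state$iteration, k = ncol(state$z),
                         alpha = state$alpha, sigma_x = state$sigma_x,
                         sigma_a = state$sigma_a, log_joint = log_joint)
  state
}

#' One Gibbs sweep over all rows
#'
#' For each row: updates every existing feature assignment via its full
#' conditional (columns whose popularity excluding the row is zero are
#' dropped atomically with the singleton redraw), then proposes new
#' singleton features; afterwards redraws the weights, resamples `alpha`
#' (conjugate Gamma) and the noise scales (Metropolis), prunes empty columns
#' and increments the iteration counter. The per-sweep trace record is
#' attached as `state$last_record`.
#'
#' Two row-update methods target the same posterior: `"accelerated"`
#' (default) evaluates flips and singleton redraws with the weights
#' integrated out (the collapsed marginal factorizes over measures, so
#' per-cell missingness is exact), which mixes far better at realistic
#' problem sizes; `"explicit"` conditions on the current weight draw.
#'
#' @param state An [ibp_state()].
#' @param x Battery or numeric matrix (NA = masked).
#' @param k_cap Maximum new features per row proposal. Default 4.
#' @param max_k Cap on the total feature count. Default `Inf`.
#' @param update_alpha,update_scales Logical; resample `alpha` and the noise
#'   scales this sweep. Defaults `TRUE`.
#' @param method `"accelerated"` (weight-collapsed row updates) or
#'   `"explicit"`.
#' @return The updated [ibp_state()].
#' @export
gibbs_sweep <- function(state, x, k_cap = 4, max_k = Inf,
                        update_alpha = TRUE, update_scales = TRUE,
                        method = c("accelerated", "explicit")) {
  md <- as_model_data(x)
  gibbs_sweep_engine(state, md, k_cap, max_k, update_alpha, update_scales,
                     match.arg(method))
}

#' Run the linear-Gaussian IBP Gibbs sampler
#'
#' Runs `sweeps` full Gibbs sweeps from a deterministic seed, starting from
#' an empty feature matrix with `alpha` initialized from `hypers` (default
#' 5). The returned trace has one record for the initial state (iteration 0)
#' plus one per completed sweep. Convergence is reported, not enforced, as
#' the length of the longest terminal window over which `K` and `alpha`
#' (rounded to 0.1) are constant.
#'
#' @param x A `standardized_battery`, any `ncog_battery`, or a numeric
#'   matrix with `NA` at missing cells.
#' @param sweeps Number of sweeps (>= 1). Default 50.
#' @param seed Integer seed controlling all randomness. Default 1.
#' @param hypers An [ibp_hyperparameters()]. When omitted, `alpha` is
#'   initialized at 5 and the observation-noise scale at the overall SD of
#'   the observed cells (exactly 1 for a z-scored battery); starting
#'   `sigma_x` at the marginal data scale lets the noise estimate anneal
#'   downward as features are discovered instead of stranding the chain.
#' @param k_cap Maximum new features per row proposal. Default 4.
#' @param max_k Cap on total feature count. Default `Inf`.
#' @param update_alpha,update_scales Logical; resample `alpha` / the noise
#'   scales each sweep. Defaults `TRUE`.
#' @param init `"empty"` (default) starts from zero features and lets the
#'   feature set grow; `"prior"` starts from a draw of Z from the IBP prior
#'   at the initial `alpha` (weights drawn from their full conditional) for
#'   an overdispersed start.
#' @param method `"accelerated"` (default; weight-collapsed row updates,
#'   exact with per-cell missingness and much better mixing) or
#'   `"explicit"` (conditions each flip on the current weight draw). Both
#'   target the same posterior; see [gibbs_sweep()].
#' @param value_window If > 0, additionally record, for features present in
#'   the final state, the average of their binary membership over the last
#'   `value_window` sweeps (`$window_values`).
#' @return A list of class `ibp_fit`: `state` (final [ibp_state()]),
#'   `trace` (data frame: iteration, k, alpha, sigma_x, sigma_a, log_joint),
#'   `convergence` (terminal stable-window length), and optionally
#'   `window_values`.
#' @export
run_ibp <- function(x, sweeps = 50, seed = 1L,
                    hypers = NULL, k_cap = 4, max_k = Inf,
                    update_alpha = TRUE, update_scales = TRUE,
                    init = c("empty", "prior"),
                    method = c("accelerated", "explicit"),
                    value_window = 0) {
  if (sweeps < 1) stop("sweeps must be >= 1", call. = FALSE)
  init <- match.arg(init)
  method <- match.arg(method)
  md <- as_model_data(x)
  if (is.null(hypers)) {
    hypers <- ibp_hyperparameters(sigma_x = stats::sd(md$xv[md$mask]))
  }
  set.seed(seed)
  z0 <- matrix(0, md$n, 0)
  if (init == "prior") {
    z0 <- ibp_prior_draw(md$n, hypers$alpha)
    if (is.finite(max_k) && ncol(z0) > max_k) {
      z0 <- z0[, seq_len(max_k), drop = FALSE]
    }
    z0 <- z0[, colSums(z0) > 0, drop = FALSE] + 0  # double for fast updates
  }
  a0 <- if (ncol(z0) > 0) {
    sample_weights_engine(z0, md, hypers$sigma_x, hypers$sigma_a)
  } else {
    matrix(0, 0, md$d)
  }
  state <- ibp_state(z0, a0, hypers, iteration = 0L, seed = seed)
  trace_mat <- matrix(NA_real_, sweeps + 1, 6,
                      dimnames = list(NULL, c("iteration", "k", "alpha",
                                              "sigma_x", "sigma_a",
                                              "log_joint")))
  resid0 <- md$xv - z0 %*% a0
  trace_mat[1, ] <- c(0, ncol(z0), hypers$alpha, hypers$sigma_x,
                      hypers$sigma_a,
                      sum(stats::dnorm(resid0[md$mask], 0, hypers$sigma_x,
                                       log = TRUE)) +
                        sum(stats::dnorm(a0, 0, hypers$sigma_a, log = TRUE)) +
                        ibp_log_prior(z0, hypers$alpha))
  window_sums <- NULL
  window_start <- sweeps - value_window + 1
  for (s in seq_len(sweeps)) {
    state <- gibbs_sweep_engine(state, md, k_cap, max_k,
                                update_alpha, update_scales, method)
    trace_mat[s + 1, ] <- state$last_record
    if (value_window > 0 && s >= window_start) {
      cur <- matrix(0, md$n, state$next_id - 1L)
      if (ncol(state$z) > 0) cur[, state$col_ids] <- state$z
      if (is.null(window_sums)) {
        window_sums <- cur
      } else {
        if (ncol(cur) > ncol(window_sums)) {
          window_sums <- cbind(window_sums,
                               matrix(0, md$n, ncol(cur) - ncol(window_sums)))
        }
        window_sums <- window_sums + cur
      }
    }
  }
  trace <- as.data.frame(trace_mat)
  fit <- list(state = state, trace = trace,
              convergence = terminal_stable_window(trace), seed = seed)
  if (value_window > 0 && ncol(state$z) > 0) {
    fit$window_values <- window_sums[, state$col_ids, drop = FALSE] /
      value_window
  }
  class(fit) <- "ibp_fit"
  fit
}

# longest terminal run of sweeps over which K and round(alpha, 1) are constant
terminal_stable_window <- function(trace) {
  n <- nrow(trace)
  if (n < 2) return(0L)
  k <- trace$k
  a <- round(trace$alpha, 1)
  len <- 1L
  for (i in seq(n - 1, 2)) {
    if (k[i] == k[n] && a[i] == a[n]) len <- len + 1L else break
  }
  len
}

#' @export
print.ibp_fit <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf(paste0("<ibp_fit> %d sweeps (seed %s): K = %d, ",
                     "alpha = %.2f, sigma_x = %.2f, sigma_a = %.2f\n"),
              nrow(x$trace) - 1, x$seed, last$k, last$alpha, last$sigma_x,
              last$sigma_a))
  cat(sprintf("  terminal stable window: %d sweep(s)\n", x$convergence))
  invisible(x)
}

#' Extract continuous feature values at the final iteration
#'
#' For each person `i` and retained feature `k`, computes the
#' full-conditional inclusion probability `P(z[i, k] = 1 | A, sigmas, row i
#' data)` at the final state — a value in \[0, 1\] expressing the extent /
#' probability of sampling the feature. A fully masked row reduces to the
#' prior `m / N`. Binary membership (used for sampling counts) is the
#' final-iteration `z`.
#'
#' @param state An [ibp_state()] (e.g. `fit$state` from [run_ibp()]).
#' @param x The battery the sampler was fit to.
#' @return A list of class `continuous_feature_values`: `values` (N x K
#'   matrix of probabilities), `z` (final binary matrix), `feature_ids`.
#' @export
continuous_feature_values <- function(state, x) {
  md <- as_model_data(x)
  z <- state$z; a <- state$a
  n <- md$n; k <- ncol(z)
  vals <- matrix(0, n, k)
  if (k > 0) {
    cs <- colSums(z)
    two_sx2 <- 2 * state$sigma_x^2
    for (i in seq_len(n)) {
      mi <- md$mask[i, ]
      r <- md$xv[i, ] - drop(z[i, ] %*% a)
      for (kk in seq_len(k)) {
        m <- cs[kk] - z[i, kk]
        if (m < 1) {
          vals[i, kk] <- 0
          next
        }
        r0 <- if (z[i, kk] == 1) r + a[kk, ] else r
        r1 <- r0 - a[kk, ]
        dll <- sum(r0[mi]^2 - r1[mi]^2) / two_sx2
        vals[i, kk] <- 1 / (1 + ((n - m) / m) * exp(-dll))
      }
    }
  }
  structure(list(values = vals, z = z,
                 feature_ids = sprintf("feature_%d", seq_len(k))),
            class = "continuous_feature_values")
}

#' Write a sampler trace to CSV
#'
#' @param fit An `ibp_fit` from [run_ibp()].
#' @param path Output CSV path.
#' @return Invisibly, the trace data frame.
#' @export
write_trace <- function(fit, path) {
  utils::write.csv(fit$trace, path, row.names = FALSE)
  invisible(fit$trace)
}
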