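## Bayesian estimation of the constant parameter vector
## theta = {N_p, kappa, sigma1, sigma2, p11, p22} by adaptive random-walk
## Metropolis on transformed parameters. A componentwise random-walk sampler
## is available as an alternative backend.

.theta_names <- c("n_potential", "kappa", "sigma1", "sigma2", "p11", "p22")

#' Prior specification for the switching model
#'
#' N_p ~ Uniform(np_low, np_high), kappa ~ Uniform(0, 1),
#' p11, p22 ~ Beta(shape1, shape2), sigma1, sigma2 ~ half-Cauchy(scale).
#' The Cauchy prior is truncated at zero since the residual scales must be
#' positive.
#'
#' @param np_low,np_high Uniform bounds for the potential population.
#' @param p_shape1,p_shape2 Beta shapes for the stay probabilities
#'   (default 5, 1).
#' @param sigma_scale Half-Cauchy scale for the residual standard
#'   deviations (default 2).
#' @return A list of class `"prior_spec"`.
#' @export
prior_spec <- function(np_low, np_high, p_shape1 = 5, p_shape2 = 1,
                       sigma_scale = 2) {
  stopifnot(np_low >= 1, np_high > np_low, p_shape1 > 0, p_shape2 > 0,
            sigma_scale > 0)
  structure(list(np_low = np_low, np_high = np_high,
                 p_shape1 = p_shape1, p_shape2 = p_shape2,
                 sigma_scale = sigma_scale),
            class = "prior_spec")
}

#' Default priors derived from a snapshot series
#'
#' The population bounds are set from the data as (N_max, 2 N_max) with
#' N_max the largest observed active-node count; the remaining priors are
#' Uniform(0, 1) for kappa, Beta(5, 1) for the stay probabilities and
#' half-Cauchy(0, 2) for the residual scales.
#'
#' @param series A [snapshot_series()] with some positive N_t.
#' @return A [prior_spec()].
#' @export
default_priors <- function(series) {
  series <- .as_series(series)
  nmax <- suppressWarnings(max(series$n_active))
  if (!is.finite(nmax) || nmax <= 0)
    stop("series has no window with active nodes; cannot set N_p bounds",
         call. = FALSE)
  prior_spec(np_low = nmax, np_high = 2 * nmax)
}

.log_half_cauchy <- function(x, scale) {
  ifelse(x > 0, log(2) + stats::dcauchy(x, 0, scale, log = TRUE), -Inf)
}

#' Log prior density of theta
#'
#' @param theta Numeric vector (n_potential, kappa, sigma1, sigma2, p11,
#'   p22) or a [theta_params()] object.
#' @param priors A [prior_spec()].
#' @return Log prior density; `-Inf` outside the support.
#' @export
log_prior <- function(theta, priors) {
  th <- if (inherits(theta, "theta_params"))
    c(theta$n_potential, theta$kappa, theta$sigma1, theta$sigma2,
      theta$p11, theta$p22) else theta
  stopifnot(inherits(priors, "prior_spec"), length(th) == 6)
  stats::dunif(th[1], priors$np_low, priors$np_high, log = TRUE) +
    stats::dunif(th[2], 0, 1, log = TRUE) +
    .log_half_cauchy(th[3], priors$sigma_scale) +
    .log_half_cauchy(th[4], priors$sigma_scale) +
    stats::dbeta(th[5], priors$p_shape1, priors$p_shape2, log = TRUE) +
    stats::dbeta(th[6], priors$p_shape1, priors$p_shape2, log = TRUE)
}

#' Log posterior density of theta given a snapshot series
#'
#' Sum of the Hamilton-filter log-likelihood and the log prior. Returns
#' `-Inf` outside the prior support or when the likelihood is not evaluable
#' at theta (for example when an observed edge count implies an activity
#' beyond the evaluable range of the activity-driven curve); sampling
#' proposals at such points are thereby rejected. An empty series
#' contributes zero log-likelihood, so the posterior reduces to the prior.
#'
#' @inheritParams log_prior
#' @param series A [snapshot_series()].
#' @param init_probs Initial state distribution for the filter.
#' @return Log posterior density (up to a constant); `-Inf` allowed.
#' @export
log_posterior <- function(theta, series, priors, init_probs = c(0.5, 0.5)) {
  th <- if (inherits(theta, "theta_params"))
    c(theta$n_potential, theta$kappa, theta$sigma1, theta$sigma2,
      theta$p11, theta$p22) else theta
  lp <- log_prior(th, priors)
  if (!is.finite(lp)) return(-Inf)
  if (nrow(series) == 0) return(lp)
  ll <- tryCatch(
    hamilton_filter(series, theta_params(th[1], th[2], th[3], th[4],
                                         th[5], th[6]),
                    init_probs = init_probs)$loglik,
    error = function(e) -Inf)
  ll + lp
}

## --- transformed parameterisation -----------------------------------------
## z = (logit of scaled N_p, logit kappa, log sigma1, log sigma2,
##      logit p11, logit p22); the sampler walks in z-space.

.z_to_theta <- function(z, priors) {
  p <- stats::plogis(z[c(1, 2, 5, 6)])
  c(priors$np_low + (priors$np_high - priors$np_low) * p[1],
    p[2], exp(z[3]), exp(z[4]), p[3], p[4])
}

.theta_to_z <- function(th, priors) {
  c(stats::qlogis((th[1] - priors$np_low) /
                    (priors$np_high - priors$np_low)),
    stats::qlogis(th[2]), log(th[3]), log(th[4]),
    stats::qlogis(th[5]), stats::qlogis(th[6]))
}

## log |d theta / d z|; the constant log(np_high - np_low) is included for
## completeness though it cancels in Metropolis ratios.
.log_jacobian <- function(z, priors) {
  lj_logit <- function(zz) -abs(zz) - 2 * log1p(exp(-abs(zz)))
  sum(lj_logit(z[c(1, 2, 5, 6)])) + z[3] + z[4] +
    log(priors$np_high - priors$np_low)
}

## Posterior mode and curvature on the z scale: BFGS from a few random
## starts, then a numerical Hessian. Gives chain starting points and the
## initial proposal covariance (Laplace approximation); falls back to a
## diagonal proposal when optimisation fails.
.laplace_init <- function(lp_z, priors, lp_theta, n_starts = 3) {
  neg <- function(z) {
    v <- lp_z(z)
    if (!is.finite(v)) 1e10 else -v
  }
  best <- NULL
  for (k in seq_len(n_starts)) {
    z0 <- .theta_to_z(.draw_init_theta(priors, lp_theta), priors)
    opt <- tryCatch(stats::optim(z0, neg, method = "BFGS",
                                 control = list(maxit = 300)),
                    error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value) &&
        (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) return(NULL)
  H <- tryCatch(stats::optimHess(best$par, neg), error = function(e) NULL)
  C <- if (!is.null(H))
    tryCatch(solve((H + t(H)) / 2), error = function(e) NULL)
  ch <- NULL
  if (!is.null(C)) {
    ev <- eigen((C + t(C)) / 2, symmetric = TRUE)
    vals <- pmin(pmax(ev$values, 1e-8), 25)
    C <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    ch <- tryCatch(chol(2.38^2 / length(best$par) * C),
                   error = function(e) NULL)
  }
  list(mode = best$par, chol = ch)
}

.draw_init_theta <- function(priors, lp_fun) {
  for (k in 1:200) {
    th <- c(stats::runif(1, priors$np_low + 0.02 * (priors$np_high - priors$np_low),
                         priors$np_high - 0.02 * (priors$np_high - priors$np_low)),
            stats::runif(1, 0.05, 0.95),
            stats::runif(1, 0.5, 10), stats::runif(1, 0.5, 10),
            stats::runif(1, 0.6, 0.98), stats::runif(1, 0.6, 0.98))
    if (is.finite(lp_fun(th))) return(th)
  }
  stop("could not find a finite-posterior starting point", call. = FALSE)
}

.run_chain_adaptive <- function(lp_z, z0, n_burn, n_keep, chol0 = NULL) {
  d <- length(z0)
  n_tot <- n_burn + n_keep
  hist <- matrix(NA_real_, n_tot, d)
  kept <- matrix(NA_real_, n_keep, d)
  chol_prop <- if (is.null(chol0)) diag(0.1, d) else chol0
  cur <- z0
  curlp <- lp_z(cur)
  n_acc <- 0L
  for (i in seq_len(n_tot)) {
    prop <- cur + drop(stats::rnorm(d) %*% chol_prop)
    plp <- lp_z(prop)
    if (is.finite(plp) && log(stats::runif(1)) < plp - curlp) {
      cur <- prop
      curlp <- plp
      n_acc <- n_acc + 1L
    }
    hist[i, ] <- cur
    if (i <= n_burn && i >= 100 && i %% 50 == 0) {
      C <- stats::cov(hist[max(1, i - 499):i, , drop = FALSE])
      C <- 2.38^2 / d * C + diag(1e-8, d)
      ch <- tryCatch(chol(C), error = function(e) NULL)
      if (!is.null(ch)) chol_prop <- ch
    }
    if (i > n_burn) kept[i - n_burn, ] <- cur
  }
  list(z = kept, acceptance = n_acc / n_tot)
}

.run_chain_componentwise <- function(lp_z, z0, n_burn, n_keep,
                                     chol0 = NULL) {
  d <- length(z0)
  n_tot <- n_burn + n_keep
  kept <- matrix(NA_real_, n_keep, d)
  scale <- if (is.null(chol0)) rep(0.2, d) else
    pmax(sqrt(colSums(chol0^2)), 1e-3)
  acc_batch <- integer(d)
  cur <- z0
  curlp <- lp_z(cur)
  n_acc <- 0L
  for (i in seq_len(n_tot)) {
    for (j in seq_len(d)) {
      prop <- cur
      prop[j] <- prop[j] + stats::rnorm(1, 0, scale[j])
      plp <- lp_z(prop)
      if (is.finite(plp) && log(stats::runif(1)) < plp - curlp) {
        cur <- prop
        curlp <- plp
        n_acc <- n_acc + 1L
        acc_batch[j] <- acc_batch[j] + 1L
      }
    }
    if (i <= n_burn && i %% 50 == 0) {
      # steer each coordinate toward ~0.44 acceptance
      rate <- acc_batch / 50
      scale <- scale * exp((rate - 0.44))
      acc_batch[] <- 0L
    }
    if (i > n_burn) kept[i - n_burn, ] <- cur
  }
  list(z = kept, acceptance = n_acc / (n_tot * d))
}

## split-chain potential scale reduction for one parameter;
## draws: list of per-chain numeric vectors
.split_rhat <- function(draws) {
  halves <- unlist(lapply(draws, function(x) {
    n <- length(x) %/% 2
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  n <- min(lengths(halves))
  halves <- lapply(halves, function(x) x[seq_len(n)])
  mns <- vapply(halves, mean, numeric(1))
  vrs <- vapply(halves, stats::var, numeric(1))
  W <- mean(vrs)
  B <- n * stats::var(mns)
  if (!is.finite(W) || W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Sample the posterior of theta by MCMC
#'
#' Runs multiple seeded chains of random-walk Metropolis targeting
#' [log_posterior()] on transformed parameters (logit for bounded
#' parameters, log for the residual scales). The default backend adapts a
#' joint proposal covariance during burn-in; the componentwise backend
#' updates one coordinate at a time with per-coordinate step adaptation.
#' Split-chain potential-scale-reduction diagnostics are computed per
#' parameter and a warning is attached (and emitted) when any exceeds 1.05.
#'
#' @param series A [snapshot_series()]; may have zero rows, in which case
#'   the prior is sampled.
#' @param priors A [prior_spec()]; defaults to [default_priors()] of the
#'   series.
#' @param n_chains Number of chains (default 4).
#' @param n_keep Kept draws per chain after burn-in (default 5000).
#' @param n_burn Burn-in draws per chain (default 5000).
#' @param seed Integer seed; the run is reproducible given it.
#' @param init_probs Initial state distribution for the filter.
#' @param sampler `"adaptive"` (joint, default) or `"componentwise"`.
#' @param fast Logical; `TRUE` shrinks the run to 500 + 500 per chain.
#' @return A list of class `"posterior_samples"`: `chains` (list of
#'   n_keep x 6 matrices), `rhat`, `acceptance`, `priors`, `seed`, and run
#'   sizes.
#' @export
run_mcmc <- function(series, priors = default_priors(series),
                     n_chains = 4, n_keep = 5000, n_burn = 5000,
                     seed = 1, init_probs = c(0.5, 0.5),
                     sampler = c("adaptive", "componentwise"),
                     fast = FALSE) {
  series <- .as_series(series)
  stopifnot(inherits(priors, "prior_spec"), n_chains >= 1, n_keep >= 1)
  sampler <- match.arg(sampler)
  if (fast) {
    n_keep <- 500
    n_burn <- 500
  }
  lp_theta <- function(th) log_posterior(th, series, priors, init_probs)
  lp_z <- function(z) {
    lp <- lp_theta(.z_to_theta(z, priors))
    if (!is.finite(lp)) return(-Inf)
    lp + .log_jacobian(z, priors)
  }
  run1 <- switch(sampler, adaptive = .run_chain_adaptive,
                 componentwise = .run_chain_componentwise)
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max %/% 2, n_chains)
  lap <- .laplace_init(lp_z, priors, lp_theta)
  chains <- vector("list", n_chains)
  acceptance <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(chain_seeds[ch])
    z0 <- if (!is.null(lap)) {
      jit <- if (is.null(lap$chol)) stats::rnorm(6, 0, 0.05) else
        0.3 * drop(stats::rnorm(6) %*% lap$chol)
      z <- lap$mode + jit
      if (is.finite(lp_z(z))) z else lap$mode
    } else .theta_to_z(.draw_init_theta(priors, lp_theta), priors)
    res <- run1(lp_z, z0, n_burn, n_keep, chol0 = if (!is.null(lap)) lap$chol)
    draws <- t(apply(res$z, 1, .z_to_theta, priors = priors))
    colnames(draws) <- .theta_names
    chains[[ch]] <- draws
    acceptance[ch] <- res$acceptance
  }
  rhat <- vapply(seq_along(.theta_names), function(j)
    .split_rhat(lapply(chains, function(m) m[, j])), numeric(1))
  names(rhat) <- .theta_names
  out <- structure(list(chains = chains, rhat = rhat,
                        acceptance = acceptance, priors = priors,
                        seed = seed, n_chains = n_chains,
                        n_keep = n_keep, n_burn = n_burn,
                        sampler = sampler,
                        converged = all(rhat < 1.05, na.rm = TRUE)),
                   class = "posterior_samples")
  if (!out$converged)
    warning("split-Rhat above 1.05 for: ",
            paste(.theta_names[rhat >= 1.05], collapse = ", "),
            call. = FALSE)
  out
}

#' Pooled draw matrix from posterior samples
#'
#' @param samples A `"posterior_samples"` object.
#' @return Matrix (total kept draws x 6), chains stacked.
#' @export
as_draws_matrix <- function(samples) {
  stopifnot(inherits(samples, "posterior_samples"))
  do.call(rbind, samples$chains)
}

#' Posterior means and central 95% credible intervals
#'
#' Chains are pooled; intervals are equal-tailed 2.5/97.5 percentiles.
#'
#' @param samples A `"posterior_samples"` object.
#' @return Data frame with columns parameter, mean, ci_low, ci_high, prior.
#' @export
posterior_summary <- function(samples) {
  draws <- as_draws_matrix(samples)
  pr <- samples$priors
  prior_lab <- c(
    sprintf("Uniform(%g, %g)", pr$np_low, pr$np_high),
    "Uniform(0, 1)",
    sprintf("Half-Cauchy(0, %g)", pr$sigma_scale),
    sprintf("Half-Cauchy(0, %g)", pr$sigma_scale),
    sprintf("Beta(%g, %g)", pr$p_shape1, pr$p_shape2),
    sprintf("Beta(%g, %g)", pr$p_shape1, pr$p_shape2))
  data.frame(
    parameter = .theta_names,
    mean = colMeans(draws),
    ci_low = apply(draws, 2, stats::quantile, probs = 0.025),
    ci_high = apply(draws, 2, stats::quantile, probs = 0.975),
    prior = prior_lab,
    row.names = NULL)
}

#' Posterior-mean parameter vector as theta_params
#'
#' @param samples A `"posterior_samples"` object.
#' @return A [theta_params()] at the pooled posterior means.
#' @export
posterior_mean_theta <- function(samples) {
  m <- colMeans(as_draws_matrix(samples))
  theta_params(m[1], m[2], m[3], m[4], m[5], m[6])
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf(
    "Posterior samples: %d chains x %d kept draws (%s sampler, seed %s)\n",
    x$n_chains, x$n_keep, x$sampler, format(x$seed)))
  cat(sprintf("  mean acceptance %.2f; max split-Rhat %.3f%s\n",
              mean(x$acceptance), max(x$rhat, na.rm = TRUE),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(posterior_summary(x), digits = 4)
  invisible(x)
}
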