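## Exact state-probability recursions for the two-regime switching model:
## Gaussian observation densities around the two regime curves, the Hamilton
## forward filter with the log-likelihood, the Kim backward smoother, and a
## brute-force path-enumeration oracle used in tests.

#' Constant parameter vector of the switching model
#'
#' Bundles theta = \{N_p, kappa, sigma1, sigma2, p11, p22\} with the derived
#' 2x2 transition matrix `P`, where `P[r, s] = Pr(S_{t+1} = s | S_t = r)`.
#'
#' @param n_potential Constant potential population N_p (Regime 2 branch).
#' @param kappa Constant overall activity (Regime 1 branch), in (0, 1].
#' @param sigma1,sigma2 Residual standard deviations of the Gaussian
#'   observation errors on N_t in each regime, > 0.
#' @param p11,p22 Stay probabilities, in (0, 1).
#' @return A list of class `"theta_params"`.
#' @export
theta_params <- function(n_potential, kappa, sigma1, sigma2, p11, p22) {
  stopifnot(sigma1 > 0, sigma2 > 0, p11 > 0, p11 <= 1, p22 > 0, p22 <= 1,
            kappa > 0, kappa <= 1, n_potential > 1)
  structure(list(n_potential = n_potential, kappa = kappa,
                 sigma1 = sigma1, sigma2 = sigma2, p11 = p11, p22 = p22,
                 transition = matrix(c(p11, 1 - p22, 1 - p11, p22), 2, 2,
                                     dimnames = list(c("from1", "from2"),
                                                     c("to1", "to2")))),
            class = "theta_params")
}

.as_theta <- function(theta) {
  if (inherits(theta, "theta_params")) return(theta)
  if (is.numeric(theta) && length(theta) == 6)
    return(theta_params(theta[1], theta[2], theta[3], theta[4],
                        theta[5], theta[6]))
  stop("theta must be a theta_params object or a numeric vector of length 6",
       call. = FALSE)
}

## T x 2 matrix of log observation densities: column s holds
## log f(D_t | S_t = s) = log Normal(N_t; h^s(M_t), sigma_s).
.log_density_matrix <- function(series, theta) {
  h1 <- regime1_curve(series$m_edges, theta$kappa)
  h2 <- regime2_curve(series$m_edges, theta$n_potential)
  cbind(stats::dnorm(series$n_active, h1, theta$sigma1, log = TRUE),
        stats::dnorm(series$n_active, h2, theta$sigma2, log = TRUE))
}

#' Regime-conditional observation density
#'
#' Gaussian density of the observed active-node count around the regime
#' curve evaluated at the observed edge count: N_t ~ Normal(h^s(M_t),
#' sigma_s), with h^1 the population-driven and h^2 the activity-driven
#' curve.
#'
#' @param n_active Observed active-node count N_t.
#' @param m_edges Observed edge count M_t.
#' @param s Regime, 1 or 2.
#' @param theta A [theta_params()] object (or numeric vector of length 6).
#' @param log Return the log density?
#' @return Non-negative density (or its log).
#' @export
regime_conditional_density <- function(n_active, m_edges, s, theta,
                                       log = FALSE) {
  theta <- .as_theta(theta)
  stopifnot(s %in% c(1, 2))
  h <- if (s == 1) regime1_curve(m_edges, theta$kappa)
       else regime2_curve(m_edges, theta$n_potential)
  sd <- if (s == 1) theta$sigma1 else theta$sigma2
  stats::dnorm(n_active, h, sd, log = log)
}

#' Hamilton filter for the two-regime switching model
#'
#' Forward recursion over the snapshot series: predicted state probabilities
#' xi_\{t|t-1\} propagate through the transition matrix, are updated by Bayes
#' rule with the regime-conditional densities, and the per-window
#' normalising constants accumulate into the log-likelihood. Computed in log
#' space so small densities do not underflow.
#'
#' @param series A [snapshot_series()].
#' @param theta A [theta_params()] object or numeric vector of length 6.
#' @param init_probs Initial state distribution Pr(S_0 = r); default
#'   `c(0.5, 0.5)`. The first predicted distribution is `t(P) %*% init_probs`.
#' @return A list of class `"filter_result"` with T x 2 matrices `predicted`
#'   and `filtered`, the scalar `loglik`, and the transition matrix.
#' @export
hamilton_filter <- function(series, theta, init_probs = c(0.5, 0.5)) {
  series <- .as_series(series)
  theta <- .as_theta(theta)
  if (length(init_probs) != 2 || any(init_probs < 0) ||
      abs(sum(init_probs) - 1) > 1e-8)
    stop("init_probs must be a probability pair", call. = FALSE)
  tt <- nrow(series)
  lf <- .log_density_matrix(series, theta)
  if (any(is.nan(lf)))
    stop("observation density not evaluable", call. = FALSE)
  p11 <- theta$p11; p22 <- theta$p22
  predicted <- matrix(NA_real_, tt, 2)
  filtered <- matrix(NA_real_, tt, 2)
  pred <- c(init_probs[1] * p11 + init_probs[2] * (1 - p22),
            init_probs[1] * (1 - p11) + init_probs[2] * p22)
  loglik <- 0
  for (t in seq_len(tt)) {
    predicted[t, ] <- pred
    lw <- log(pred) + lf[t, ]
    mx <- max(lw)
    if (!is.finite(mx))
      stop("both regime densities vanished at window ", t,
           "; observation numerically impossible under theta", call. = FALSE)
    lc <- mx + log(sum(exp(lw - mx)))
    loglik <- loglik + lc
    filt <- exp(lw - lc)
    filtered[t, ] <- filt
    pred <- c(filt[1] * p11 + filt[2] * (1 - p22),
              filt[1] * (1 - p11) + filt[2] * p22)
  }
  structure(list(predicted = predicted, filtered = filtered,
                 loglik = loglik, transition = theta$transition,
                 init_probs = init_probs),
            class = "filter_result")
}

#' Kim fixed-interval smoother
#'
#' Backward recursion turning filtered probabilities Pr(S_t | data up to t)
#' into smoothed probabilities Pr(S_t | full series):
#' `xi_\{t|T\} = xi_\{t|t\} * (P (xi_\{t+1|T\} / xi_\{t+1|t\}))`,
#' initialised at `xi_\{T|T\}`.
#'
#' @param filter_result A `"filter_result"` from [hamilton_filter()].
#' @param transition Optional 2x2 transition matrix; defaults to the one
#'   recorded in the filter result.
#' @return T x 2 matrix of smoothed state probabilities; rows sum to 1.
#' @export
kim_smoother <- function(filter_result, transition = NULL) {
  stopifnot(inherits(filter_result, "filter_result"))
  P <- if (is.null(transition)) filter_result$transition else transition
  filt <- filter_result$filtered
  pred <- filter_result$predicted
  tt <- nrow(filt)
  smoothed <- matrix(NA_real_, tt, 2)
  smoothed[tt, ] <- filt[tt, ]
  if (tt > 1) {
    for (t in (tt - 1):1) {
      if (any(pred[t + 1, ] <= 0))
        stop("zero predicted probability at window ", t + 1,
             "; smoother division undefined", call. = FALSE)
      ratio <- smoothed[t + 1, ] / pred[t + 1, ]
      sm <- filt[t, ] * drop(P %*% ratio)
      smoothed[t, ] <- sm / sum(sm)
    }
  }
  smoothed
}

#' Exact state posterior by path enumeration (test oracle)
#'
#' Enumerates all 2^T regime paths and sums their joint weights (Markov path
#' prior times the product of observation densities) to give exact marginal
#' state probabilities per window and the exact log-likelihood. Independent
#' of the filter/smoother recursions; intended for small T.
#'
#' @inheritParams hamilton_filter
#' @param max_windows Refuse longer series than this (default 15).
#' @return List with T x 2 `marginals` and scalar `loglik`.
#' @export
brute_force_state_posterior <- function(series, theta,
                                        init_probs = c(0.5, 0.5),
                                        max_windows = 15) {
  series <- .as_series(series)
  theta <- .as_theta(theta)
  tt <- nrow(series)
  if (tt > max_windows)
    stop("refusing to enumerate 2^", tt, " paths", call. = FALSE)
  lf <- .log_density_matrix(series, theta)
  P <- theta$transition
  pi1 <- drop(t(P) %*% init_probs)
  paths <- as.matrix(expand.grid(rep(list(1:2), tt)))
  logw <- vapply(seq_len(nrow(paths)), function(k) {
    s <- paths[k, ]
    lp <- log(pi1[s[1]]) + lf[1, s[1]]
    if (tt > 1)
      for (t in 2:tt) lp <- lp + log(P[s[t - 1], s[t]]) + lf[t, s[t]]
    lp
  }, numeric(1))
  mx <- max(logw)
  w <- exp(logw - mx)
  loglik <- mx + log(sum(w))
  w <- w / sum(w)
  marginals <- t(vapply(seq_len(tt), function(t)
    c(sum(w[paths[, t] == 1]), sum(w[paths[, t] == 2])), numeric(2)))
  list(marginals = marginals, loglik = loglik)
}
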