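## Posterior regime probabilities per window, three-way classification, and
## reconstruction of the time-varying population and activity paths.

#' Smoothed regime-1 probabilities per posterior draw
#'
#' Runs the Hamilton filter and Kim smoother once per kept posterior draw
#' (optionally thinned) and collects Pr(S_t = 1 | full series; theta_draw).
#' Draws at which the filter fails are dropped with a warning and recorded
#' in the `"failed_draws"` attribute.
#'
#' @param samples A `"posterior_samples"` object.
#' @param series The fitted [snapshot_series()].
#' @param init_probs Initial state distribution for the filter.
#' @param thin Keep every `thin`-th pooled draw (default 1 = all); the
#'   thinning factor is recorded in the `"thin"` attribute.
#' @return Matrix (used draws x T) of smoothed regime-1 probabilities.
#' @export
smoothed_prob_draws <- function(samples, series, init_probs = c(0.5, 0.5),
                                thin = 1) {
  stopifnot(inherits(samples, "posterior_samples"), thin >= 1)
  series <- .as_series(series)
  draws <- as_draws_matrix(samples)
  idx <- seq(1, nrow(draws), by = thin)
  out <- matrix(NA_real_, length(idx), nrow(series))
  failed <- logical(length(idx))
  for (k in seq_along(idx)) {
    th <- draws[idx[k], ]
    sm <- tryCatch({
      fr <- hamilton_filter(series, th, init_probs)
      kim_smoother(fr)[, 1]
    }, error = function(e) NULL)
    if (is.null(sm)) failed[k] <- TRUE else out[k, ] <- sm
  }
  if (any(failed)) {
    warning(sum(failed), " draw(s) failed filtering and were dropped",
            call. = FALSE)
    out <- out[!failed, , drop = FALSE]
  }
  attr(out, "thin") <- thin
  attr(out, "failed_draws") <- which(failed)
  out
}

#' Three-way regime classification of windows
#'
#' A window is labelled `"regime1"` when more than `frac_threshold` of the
#' posterior draws put its smoothed regime-1 probability above
#' `prob_threshold`; `"regime2"` symmetrically below; otherwise the window
#' falls in the undetermined `"gray"` area.
#'
#' @param prob_draws Draws x T matrix from [smoothed_prob_draws()].
#' @param prob_threshold Probability cut (default 0.5).
#' @param frac_threshold Required fraction of draws (default 0.95).
#' @return Character vector of per-window labels.
#' @export
classify_windows <- function(prob_draws, prob_threshold = 0.5,
                             frac_threshold = 0.95) {
  stopifnot(is.matrix(prob_draws), nrow(prob_draws) > 0)
  frac1 <- colMeans(prob_draws > prob_threshold)
  frac2 <- colMeans(prob_draws < prob_threshold)
  ifelse(frac1 > frac_threshold, "regime1",
         ifelse(frac2 > frac_threshold, "regime2", "gray"))
}

## One path evaluation at a single theta and probability vector:
## population branch uses the inverse map at the draw's kappa, activity
## branch the inverse map at the draw's N_p; the smoothed probability mixes
## the branches.
.paths_at <- function(theta, prob1, m_edges) {
  np_branch <- invert_population(m_edges, theta[2])
  kap_branch <- invert_activity(m_edges, theta[1])
  list(np = prob1 * np_branch + (1 - prob1) * theta[1],
       kappa = prob1 * theta[2] + (1 - prob1) * kap_branch)
}

#' Reconstruct time-varying population and activity paths
#'
#' Point paths evaluate the probability-weighted mixture of the two regime
#' branches at the pooled posterior mean theta-hat: in each window the
#' population estimate mixes the inverse-map value N_p(M_t, kappa-hat) with
#' the constant N_p-hat, weighted by the smoothed regime probabilities, and
#' symmetrically for the activity. Credible bands are 2.5/97.5 percentiles
#' of the same evaluation per posterior draw.
#'
#' @param samples A `"posterior_samples"` object.
#' @param series The fitted [snapshot_series()].
#' @param prob_draws Draws x T matrix from [smoothed_prob_draws()] (thinned
#'   matrices are matched to the same thinned draws).
#' @param init_probs Initial state distribution for the point-path
#'   smoothing at theta-hat.
#' @return Data frame of class `"parameter_paths"` with columns
#'   window_start, np_hat, np_lo, np_hi, kappa_hat, kappa_lo, kappa_hi and
#'   the point smoothed probability prob_regime1.
#' @export
parameter_paths <- function(samples, series, prob_draws,
                            init_probs = c(0.5, 0.5)) {
  stopifnot(inherits(samples, "posterior_samples"), is.matrix(prob_draws))
  series <- .as_series(series)
  draws <- as_draws_matrix(samples)
  thin <- attr(prob_draws, "thin")
  idx <- seq(1, nrow(draws), by = if (is.null(thin)) 1 else thin)
  failed <- attr(prob_draws, "failed_draws")
  if (length(failed)) idx <- idx[-failed]
  if (length(idx) != nrow(prob_draws))
    stop("prob_draws does not match the posterior draws", call. = FALSE)

  theta_hat <- posterior_mean_theta(samples)
  th_vec <- c(theta_hat$n_potential, theta_hat$kappa, theta_hat$sigma1,
              theta_hat$sigma2, theta_hat$p11, theta_hat$p22)
  p1_hat <- kim_smoother(hamilton_filter(series, theta_hat, init_probs))[, 1]
  point <- .paths_at(th_vec, p1_hat, series$m_edges)

  np_mat <- matrix(NA_real_, length(idx), nrow(series))
  kap_mat <- matrix(NA_real_, length(idx), nrow(series))
  for (k in seq_along(idx)) {
    pk <- .paths_at(draws[idx[k], ], prob_draws[k, ], series$m_edges)
    np_mat[k, ] <- pk$np
    kap_mat[k, ] <- pk$kappa
  }
  qs <- function(m, p) apply(m, 2, stats::quantile, probs = p)
  structure(
    data.frame(window_start = series$window_start,
               prob_regime1 = p1_hat,
               np_hat = point$np,
               np_lo = qs(np_mat, 0.025), np_hi = qs(np_mat, 0.975),
               kappa_hat = point$kappa,
               kappa_lo = qs(kap_mat, 0.025), kappa_hi = qs(kap_mat, 0.975)),
    class = c("parameter_paths", "data.frame"))
}

#' Observed per-window network density with regime labels
#'
#' Density is 2M/(N(N-1)); windows with fewer than two active nodes get a
#' missing value.
#'
#' @param series A [snapshot_series()].
#' @param labels Optional per-window labels from [classify_windows()].
#' @return Data frame with window_start, n_active, m_edges, density, label.
#' @export
density_report <- function(series, labels = NULL) {
  series <- .as_series(series)
  dens <- ifelse(series$n_active > 1,
                 2 * series$m_edges /
                   (series$n_active * (series$n_active - 1)),
                 NA_real_)
  data.frame(window_start = series$window_start,
             n_active = series$n_active, m_edges = series$m_edges,
             density = dens,
             label = if (is.null(labels)) NA_character_ else labels)
}

#' Full per-window regime report
#'
#' Joins the observed counts, posterior-mean smoothed probability with its
#' credible band, the three-way classification, the reconstructed parameter
#' paths and the observed density into one table (one row per window).
#'
#' @inheritParams parameter_paths
#' @param prob_threshold,frac_threshold Classification thresholds, see
#'   [classify_windows()].
#' @return Data frame with columns window_start, N, M, prob_regime1_mean,
#'   prob_ci_low, prob_ci_high, label, np_hat, np_lo, np_hi, kappa_hat,
#'   kappa_lo, kappa_hi, density.
#' @export
regime_report <- function(samples, series, prob_draws,
                          init_probs = c(0.5, 0.5),
                          prob_threshold = 0.5, frac_threshold = 0.95) {
  series <- .as_series(series)
  labels <- classify_windows(prob_draws, prob_threshold, frac_threshold)
  paths <- parameter_paths(samples, series, prob_draws, init_probs)
  dens <- density_report(series, labels)
  data.frame(window_start = series$window_start,
             N = series$n_active, M = series$m_edges,
             prob_regime1_mean = colMeans(prob_draws),
             prob_ci_low = apply(prob_draws, 2, stats::quantile, 0.025),
             prob_ci_high = apply(prob_draws, 2, stats::quantile, 0.975),
             label = labels,
             np_hat = paths$np_hat, np_lo = paths$np_lo,
             np_hi = paths$np_hi,
             kappa_hat = paths$kappa_hat, kappa_lo = paths$kappa_lo,
             kappa_hi = paths$kappa_hi,
             density = dens$density)
}
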