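# Shared fixtures, all generated in code.

# A small valid observation series with contact-network-like sparsity
# (mean degree a few contacts per node, well below the complete graph).
make_test_series <- function(n = 6, seed = 1) {
  set.seed(seed)
  n_active <- sample(10:60, n, replace = TRUE)
  m_edges <- vapply(n_active, function(k)
    sample(ceiling(k / 2):min(3 * k, k * (k - 1) / 2), 1), numeric(1))
  snapshot_series(window_start = (seq_len(n) - 1) * 600,
                  n_active = n_active, m_edges = m_edges)
}

# A random admissible parameter vector for the switching model.
make_test_theta <- function(seed = 1) {
  set.seed(seed)
  theta_params(n_potential = runif(1, 60, 120),
               kappa = runif(1, 0.1, 0.9),
               sigma1 = runif(1, 2, 12), sigma2 = runif(1, 2, 12),
               p11 = runif(1, 0.6, 0.98), p22 = runif(1, 0.6, 0.98))
}

# Posterior-samples object with externally fixed draws, for tests that need
# known draws rather than a fitted object.
make_samples <- function(draw_matrix, priors, n_chains = 2) {
  draws_per_chain <- nrow(draw_matrix) / n_chains
  chains <- lapply(seq_len(n_chains), function(ch) {
    m <- draw_matrix[(ch - 1) * draws_per_chain + seq_len(draws_per_chain), ,
                     drop = FALSE]
    colnames(m) <- c("n_potential", "kappa", "sigma1", "sigma2",
                     "p11", "p22")
    m
  })
  structure(list(chains = chains, rhat = rep(1, 6),
                 acceptance = rep(NA_real_, n_chains), priors = priors,
                 seed = NA_integer_, n_chains = n_chains,
                 n_keep = draws_per_chain, n_burn = 0L,
                 sampler = "fixed", converged = TRUE),
            class = "posterior_samples")
}

theta_as_vector <- function(theta) {
  c(theta$n_potential, theta$kappa, theta$sigma1, theta$sigma2,
    theta$p11, theta$p22)
}
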