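test_that("default priors follow the N_max rule", {
  ser <- snapshot_series(c(0, 600, 1200), c(10, 50, 30), c(20, 300, 80))
  pr <- default_priors(ser)
  expect_equal(pr$np_low, 50)
  expect_equal(pr$np_high, 100)
  # Beta(5, 1) stay-probability prior has mean 5/6
  expect_equal(pr$p_shape1 / (pr$p_shape1 + pr$p_shape2), 5 / 6)
  ser0 <- snapshot_series(numeric(0), integer(0), integer(0))
  expect_error(default_priors(ser0), "active nodes")
})

test_that("log posterior decomposes into filter likelihood plus log prior", {
  ser <- make_test_series(5, seed = 3)
  pr <- default_priors(ser)
  th <- c(1.4 * pr$np_low, 0.45, 6, 7, 0.9, 0.85)
  ll <- hamilton_filter(ser, th)$loglik
  expect_equal(log_posterior(th, ser, pr), ll + log_prior(th, pr))
  # term-by-term prior decomposition
  expect_equal(log_prior(th, pr),
               dunif(th[1], pr$np_low, pr$np_high, log = TRUE) +
                 dunif(th[2], 0, 1, log = TRUE) +
                 log(2) + dcauchy(th[3], 0, 2, log = TRUE) +
                 log(2) + dcauchy(th[4], 0, 2, log = TRUE) +
                 dbeta(th[5], 5, 1, log = TRUE) +
                 dbeta(th[6], 5, 1, log = TRUE))
  # outside support
  expect_identical(log_posterior(c(th[1], 0.45, -1, 7, 0.9, 0.85), ser, pr),
                   -Inf)
  expect_identical(log_posterior(c(0.5 * pr$np_low, 0.45, 6, 7, 0.9, 0.85),
                                 ser, pr), -Inf)
  expect_identical(log_posterior(c(th[1], 1.2, 6, 7, 0.9, 0.85), ser, pr),
                   -Inf)
})

test_that("the likelihood is sequence-aware: permuting windows changes it", {
  ser <- make_test_series(5, seed = 9)
  pr <- default_priors(ser)
  th <- c(1.3 * pr$np_low, 0.4, 5, 5, 0.9, 0.9)
  perm <- snapshot_series(ser$window_start, ser$n_active[c(3, 1, 5, 2, 4)],
                          ser$m_edges[c(3, 1, 5, 2, 4)])
  expect_false(isTRUE(all.equal(log_posterior(th, ser, pr),
                                log_posterior(th, perm, pr))))
})

test_that("sampling with a constant likelihood reproduces the priors", {
  empty <- snapshot_series(numeric(0), integer(0), integer(0))
  pr <- prior_spec(50, 100)
  fit <- suppressWarnings(run_mcmc(empty, pr, n_chains = 4, n_keep = 800,
                                   n_burn = 500, seed = 11))
  s <- posterior_summary(fit)
  expect_equal(s$mean[s$parameter == "p11"], 5 / 6, tolerance = 0.03)
  expect_equal(s$mean[s$parameter == "kappa"], 0.5, tolerance = 0.04)
  expect_equal(s$mean[s$parameter == "n_potential"], 75, tolerance = 0.03)
  expect_equal(s$ci_low[s$parameter == "kappa"], 0.025, tolerance = 0.03)
  expect_equal(s$ci_high[s$parameter == "kappa"], 0.975, tolerance = 0.03)
})

test_that("MCMC is reproducible and respects the prior support", {
  cfg <- sim_config(60, 0.4, 0.9, 0.9, n_windows = 40, seed = 21)
  ser <- simulate_series(cfg)$series
  f1 <- suppressWarnings(run_mcmc(ser, n_chains = 2, n_keep = 150,
                                  n_burn = 150, seed = 5))
  f2 <- suppressWarnings(run_mcmc(ser, n_chains = 2, n_keep = 150,
                                  n_burn = 150, seed = 5))
  expect_identical(f1$chains, f2$chains)
  d <- as_draws_matrix(f1)
  expect_equal(nrow(d), 300)
  pr <- f1$priors
  expect_true(all(d[, "n_potential"] > pr$np_low &
                    d[, "n_potential"] < pr$np_high))
  expect_true(all(d[, "kappa"] > 0 & d[, "kappa"] < 1))
  expect_true(all(d[, c("sigma1", "sigma2")] > 0))
  expect_true(all(d[, c("p11", "p22")] > 0 & d[, c("p11", "p22")] < 1))
})

test_that("joint and componentwise samplers agree on posterior means", {
  cfg <- sim_config(100, 0.35, 0.93, 0.93, n_windows = 80, seed = 31)
  ser <- simulate_series(cfg)$series
  fa <- suppressWarnings(run_mcmc(ser, n_chains = 2, n_keep = 400,
                                  n_burn = 400, seed = 13,
                                  sampler = "adaptive"))
  fc <- suppressWarnings(run_mcmc(ser, n_chains = 2, n_keep = 400,
                                  n_burn = 400, seed = 13,
                                  sampler = "componentwise"))
  ma <- colMeans(as_draws_matrix(fa))
  mc <- colMeans(as_draws_matrix(fc))
  expect_equal(ma[["n_potential"]], mc[["n_potential"]], tolerance = 0.02)
  expect_equal(ma[["kappa"]], mc[["kappa"]], tolerance = 0.1)
  expect_lt(abs(ma[["p11"]] - mc[["p11"]]), 0.05)
  expect_lt(abs(ma[["p22"]] - mc[["p22"]]), 0.05)
})

test_that("credible intervals cover the generating parameters across replicates", {
  hits <- matrix(NA, 10, 4,
                 dimnames = list(NULL, c("n_potential", "kappa", "p11", "p22")))
  truth <- c(n_potential = 120, kappa = 0.35, p11 = 0.92, p22 = 0.92)
  for (r in 1:10) {
    cfg <- sim_config(truth[["n_potential"]], truth[["kappa"]],
                      truth[["p11"]], truth[["p22"]],
                      n_windows = 120, seed = 400 + r)
    ser <- simulate_series(cfg)$series
    fit <- suppressWarnings(run_mcmc(ser, n_chains = 3, n_keep = 600,
                                     n_burn = 1500, seed = 500 + r))
    s <- posterior_summary(fit)
    for (p in colnames(hits)) {
      row <- s[s$parameter == p, ]
      hits[r, p] <- row$ci_low <= truth[[p]] && truth[[p]] <= row$ci_high
    }
  }
  expect_true(all(colMeans(hits) >= 0.8))
})

test_that("posterior summaries use pooled equal-tailed percentiles", {
  pr <- prior_spec(50, 100)
  const <- matrix(rep(c(60, 0.5, 2, 3, 0.9, 0.8), each = 40), ncol = 6)
  s <- posterior_summary(make_samples(const, pr))
  expect_equal(s$mean, c(60, 0.5, 2, 3, 0.9, 0.8))
  expect_equal(s$ci_high - s$ci_low, rep(0, 6))
  d100 <- matrix(rep(c(60, 0.5, 2, 3, 0.9, 0.8), each = 100), ncol = 6)
  d100[, 1] <- 1:100
  pr2 <- prior_spec(1, 200)
  s2 <- posterior_summary(make_samples(d100, pr2))
  expect_equal(s2$ci_low[1], unname(quantile(1:100, 0.025)))
  expect_equal(s2$ci_high[1], unname(quantile(1:100, 0.975)))
  expect_equal(s2$ci_low[1], 3.475)
  expect_equal(s2$ci_high[1], 97.525)
})
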