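test_that("window classification follows the draw-fraction rule", {
  pd <- rbind(rep(0.99, 3), rep(0.99, 3), rep(0.99, 3))
  pd[, 2] <- 0.01
  pd[, 3] <- c(0.9, 0.1, 0.9) # draws straddle the cut -> gray
  expect_equal(classify_windows(pd), c("regime1", "regime2", "gray"))
  # threshold behaviour: exactly at the fraction is not enough
  half <- matrix(rep(c(0.9, 0.1), each = 10), ncol = 1)
  expect_equal(classify_windows(half), "gray")
  expect_equal(classify_windows(half, frac_threshold = 0.4), "regime1")
})

test_that("per-draw smoothing matches direct filter+smoother calls", {
  ser <- make_test_series(8, seed = 15)
  pr <- default_priors(ser)
  th <- c(1.5 * pr$np_low, 0.4, 6, 6, 0.9, 0.9)
  draws <- matrix(rep(th, each = 20), ncol = 6)
  samples <- make_samples(draws, pr)
  pd <- smoothed_prob_draws(samples, ser)
  direct <- kim_smoother(hamilton_filter(ser, th))[, 1]
  expect_equal(nrow(pd), 20)
  for (k in seq_len(nrow(pd))) expect_equal(pd[k, ], direct)
  # thinning keeps every k-th draw and records the factor
  pd4 <- smoothed_prob_draws(samples, ser, thin = 4)
  expect_equal(nrow(pd4), 5)
  expect_equal(attr(pd4, "thin"), 4)
})

test_that("smoothed probabilities at the true parameters track the true states", {
  cfg <- sim_config(200, 0.3, 0.95, 0.95, n_windows = 150, seed = 77)
  sim <- simulate_series(cfg)
  th <- theta_params(200, 0.3, 6, 4, 0.95, 0.95)
  p1 <- kim_smoother(hamilton_filter(sim$series, th))[, 1]
  agree <- (p1 > 0.5) == (sim$states == 1L)
  expect_gte(mean(agree), 0.9)
})

test_that("parameter paths mix the two regime branches by the smoothed probability", {
  ser <- make_test_series(6, seed = 23)
  pr <- default_priors(ser)
  th <- c(1.5 * pr$np_low, 0.4, 6, 6, 0.9, 0.9)
  draws <- matrix(rep(th, each = 16), ncol = 6)
  samples <- make_samples(draws, pr)
  pd <- smoothed_prob_draws(samples, ser)
  paths <- parameter_paths(samples, ser, pd)
  p1 <- kim_smoother(hamilton_filter(ser, th))[, 1]
  np_branch <- invert_population(ser$m_edges, th[2])
  kap_branch <- invert_activity(ser$m_edges, th[1])
  expect_equal(paths$np_hat, p1 * np_branch + (1 - p1) * th[1])
  expect_equal(paths$kappa_hat, p1 * th[2] + (1 - p1) * kap_branch)
  # identical draws collapse the credible band onto the point path
  expect_equal(paths$np_lo, paths$np_hat)
  expect_equal(paths$np_hi, paths$np_hat)
  expect_equal(paths$kappa_lo, paths$kappa_hat)
  # degenerate mixing weights recover the pure branches
  expect_equal(p1 * np_branch + (1 - p1) * th[1],
               ifelse(p1 == 1, np_branch, p1 * np_branch + (1 - p1) * th[1]))
  expect_true(all(paths$np_hat >= 1))
  expect_true(all(paths$kappa_hat >= 0))
})

test_that("recovered population path follows the decaying truth in regime-1 stretches", {
  cfg <- sim_config(200, 0.3, 0.97, 0.85, n_windows = 120, seed = 55)
  sim <- simulate_series(cfg)
  pr <- default_priors(sim$series)
  th <- c(200, 0.3, 6, 4, 0.97, 0.85)
  samples <- make_samples(matrix(rep(th, each = 16), ncol = 6), pr)
  pd <- smoothed_prob_draws(samples, sim$series)
  paths <- parameter_paths(samples, sim$series, pd)
  r1 <- sim$states == 1L
  expect_gte(sum(r1), 10)
  expect_gte(cor(paths$np_hat[r1], sim$np_path[r1], method = "spearman"),
             0.8)
})

test_that("density report computes 2M/(N(N-1)) with missing values below two nodes", {
  ser <- snapshot_series(c(0, 600, 1200), c(2, 0, 4), c(1, 0, 3))
  rep_tab <- density_report(ser, labels = c("regime1", "gray", "regime2"))
  expect_equal(rep_tab$density, c(1, NA, 0.5))
  expect_equal(rep_tab$label[3], "regime2")
})

test_that("the full regime report carries the documented columns", {
  ser <- make_test_series(5, seed = 40)
  pr <- default_priors(ser)
  th <- c(1.5 * pr$np_low, 0.4, 6, 6, 0.9, 0.9)
  samples <- make_samples(matrix(rep(th, each = 16), ncol = 6), pr)
  pd <- smoothed_prob_draws(samples, ser)
  tab <- regime_report(samples, ser, pd)
  expect_named(tab, c("window_start", "N", "M", "prob_regime1_mean",
                      "prob_ci_low", "prob_ci_high", "label", "np_hat",
                      "np_lo", "np_hi", "kappa_hat", "kappa_lo", "kappa_hi",
                      "density"))
  expect_true(all(tab$label %in% c("regime1", "regime2", "gray")))
})
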