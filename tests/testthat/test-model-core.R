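test_that("pairwise contact probability is the kappa-weighted activity product", {
  expect_equal(edge_probability(1, 1, 1), 1)
  expect_equal(edge_probability(0.3, 0, 0.8), 0)
  expect_equal(edge_probability(0.3, 0.5, 0.5), 0.075)
  expect_error(edge_probability(0, 0.5, 0.5), "kappa")
  expect_error(edge_probability(1.2, 0.5, 0.5), "kappa")
  expect_error(edge_probability(0.5, 1.5, 0.5), "activities")
})

test_that("isolated fraction matches hand values and boundary cases", {
  expect_equal(isolated_fraction(0.7, 1), 1)
  expect_equal(isolated_fraction(0.123, 1), 1)
  expect_equal(isolated_fraction(1, 2), 0.75)
  expect_error(isolated_fraction(-0.1, 10), "kappa")
  expect_error(isolated_fraction(2.5, 10), "kappa")
  expect_error(isolated_fraction(0.5, 0.5), "n_potential")
})

test_that("closed-form q0 and mean degree agree with quadrature of the activity integrals", {
  grid <- expand.grid(kappa = c(0.05, 0.2, 0.45, 0.8, 1),
                      np = c(2, 5, 17, 60, 250))
  for (r in seq_len(nrow(grid))) {
    k <- grid$kappa[r]; np <- grid$np[r]
    q0_quad <- integrate(function(a) (1 - k * a / 2)^(np - 1), 0, 1,
                         rel.tol = 1e-12)$value
    expect_equal(isolated_fraction(k, np), q0_quad, tolerance = 1e-10)
    kbar_quad <- (np - 1) * integrate(function(a) {
      vapply(a, function(ai)
        integrate(function(ap) k * ai * ap, 0, 1, rel.tol = 1e-12)$value,
        numeric(1))
    }, 0, 1, rel.tol = 1e-12)$value
    expect_equal(mean_degree(k, np), kbar_quad, tolerance = 1e-10)
  }
})

test_that("expected node and edge counts match hand arithmetic", {
  expect_equal(expected_active_nodes(0.7, 1), 0)
  expect_equal(expected_active_nodes(1, 2), 0.5)
  # two-node direct expectation: N = 2 * P(edge) = 2 * kappa * E[a]^2
  expect_equal(expected_active_nodes(1, 2), 2 * 1 * 0.25)
  # q0 -> 0 for large populations, so nearly everyone is active
  expect_gt(expected_active_nodes(0.467, 1e6) / 1e6, 0.999)
  expect_equal(expected_edges(0.7, 1), 0)
  expect_equal(expected_edges(0.3, 126), 590.625)
  expect_equal(expected_edges(1, 2), 0.25)
  expect_equal(mean_degree(0.3, 126), 9.375)
  expect_equal(mean_degree(0.8, 1), 0)
})

test_that("population/activity conservation identities hold to 1e-12", {
  grid <- expand.grid(kappa = seq(0.05, 1, length.out = 8),
                      np = c(2, 3, 10, 47, 126, 500))
  q0 <- isolated_fraction(grid$kappa, grid$np)
  n <- expected_active_nodes(grid$kappa, grid$np)
  m <- expected_edges(grid$kappa, grid$np)
  kbar <- mean_degree(grid$kappa, grid$np)
  expect_equal(n, (1 - q0) * grid$np, tolerance = 1e-12)
  expect_equal(kbar, 2 * m / grid$np, tolerance = 1e-12)
})

test_that("inverse maps recover the population and the activity exactly", {
  expect_equal(invert_population(0, 0.4), 1)
  expect_equal(invert_population(590.625, 0.3), 126)
  expect_equal(invert_population(0.25, 1), 2)
  expect_error(invert_population(-1, 0.3), "m_edges")
  expect_equal(invert_activity(0, 50), 0)
  expect_equal(invert_activity(590.625, 126), 0.3)
  np <- 37
  expect_equal(invert_activity(np * (np - 1) / 8, np), 1)
  expect_error(invert_activity(5, 1), "n_potential")
  # raw implied kappa above 1 is returned, not clamped
  expect_gt(invert_activity(100, 10), 1)
  # round trips across a parameter grid
  for (k in c(0.1, 0.35, 0.9)) for (np in c(2.5, 20, 300)) {
    m <- expected_edges(k, np)
    expect_equal(invert_population(m, k), np, tolerance = 1e-10)
    expect_equal(invert_activity(m, np), k, tolerance = 1e-10)
  }
})

test_that("regime curves compose the inverse maps and behave monotonically", {
  expect_equal(regime1_curve(0, 0.6), 0)
  expect_equal(regime1_curve(0.25, 1), 0.5)
  expect_equal(regime2_curve(0, 80), 0)
  expect_equal(regime2_curve(0.25, 2), 0.5)
  m_grid <- seq(0, 400, by = 5)
  h1 <- regime1_curve(m_grid, 0.3)
  expect_true(all(diff(h1) > 0))
  h2 <- regime2_curve(seq(0, 80 * 79 / 4, length.out = 50), 80)
  expect_true(all(h2 <= 80))
  expect_error(regime2_curve(1e6, 30), "implied kappa")
})

test_that("closed-form density equals 2M/(N(N-1)) and approaches kappa/4", {
  for (k in c(0.1, 0.3, 0.8)) for (np in c(10, 126, 1000)) {
    n <- expected_active_nodes(k, np)
    m <- expected_edges(k, np)
    expect_equal(expected_density(k, np), 2 * m / (n * (n - 1)),
                 tolerance = 1e-12)
  }
  expect_lt(abs(expected_density(0.4, 1e5) - 0.1), 1e-3)
  # population-driven direction: density decreases toward kappa/4 in N_p
  d <- expected_density(0.3, c(50, 100, 1000, 1e4))
  expect_true(all(diff(d) < 0))
  expect_gt(min(d), 0.3 / 4)
  expect_error(expected_density(0.05, 2), "density")
})
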