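test_that("drift equals the one-generation frequency change", {
  trip <- random_triples(25, seed = 21)
  x <- seq(0, 1, length.out = 101)
  for (i in seq_len(nrow(trip))) {
    p <- ratchet_params(trip$N[i], trip$mu[i], trip$sigma[i])
    expect_lt(max(abs(drift_M(x, p) -
                        (deterministic_map(x, p$mu, p$sigma) - x))), 1e-12)
  }

  p <- fix_clicking()
  expect_identical(drift_M(0, p), 0)
  p2 <- deterministic_fixed_points(p)[[2]]
  expect_lt(abs(drift_M(p2, p)), 1e-15)
  # outflux at fixation: -mu (1 - sigma) / (1 - sigma mu)
  expect_equal(drift_M(1, p), -0.019 / 0.999, tolerance = 1e-15)
})

test_that("sampling variance and diffusion follow the binomial law", {
  p <- fix_clicking()
  expect_identical(variance_V(c(0, 1), p), c(0, 0))
  expect_equal(variance_V(0.5, p), 0.005, tolerance = 1e-15)
  expect_equal(diffusion_D(0.3, p), variance_V(0.3, p) / 2)
  x <- seq(0.01, 0.99, by = 0.01)
  expect_equal(x[which.max(variance_V(x, p))], 0.5)
})

test_that("directional transition rate combines drift and diffusion gradient", {
  p <- fix_clicking()
  # the derivative term vanishes at x = 1/2
  expect_equal(rate_f(0.5, p), drift_M(0.5, p), tolerance = 1e-15)
  expect_equal(rate_f(0.3, p),
               drift_M(0.3, p) - (1 - 2 * 0.3) / (2 * p$N),
               tolerance = 1e-15)
  # epsilon scales only the gradient term
  p2 <- ratchet_params(50, 0.02, 0.05, epsilon = 2)
  expect_equal(rate_f(0.3, p2),
               drift_M(0.3, p2) - 2 * (1 - 2 * 0.3) / (2 * p$N),
               tolerance = 1e-15)
})

test_that("landscape diverges upward at the absorbing boundary", {
  p <- fix_clicking()
  phis <- potential_phi(c(1e-4, 1e-3, 1e-2), p)
  expect_true(all(diff(phis) < 0))
  expect_error(potential_phi(0, p), "strictly inside")
  expect_error(potential_phi(1, p), "strictly inside")
})

test_that("barrier height matches an independent quadrature of f/D", {
  p <- fix_clicking()
  rep <- classify_regime(p)
  x1 <- Re(rep$x1); x2 <- Re(rep$x2)
  dphi_closed <- potential_phi(x2, p) - potential_phi(x1, p)
  # oracle: Phi is the integral of f/D, so the barrier is the line integral
  dphi_quad <- integrate(function(x) rate_f(x, p) / diffusion_D(x, p),
                         x1, x2, rel.tol = 1e-10)$value
  expect_equal(dphi_quad, dphi_closed, tolerance = 1e-8)
  expect_equal(dphi_closed, 0.38, tolerance = 0.02 / 0.38)
})

test_that("closed-form landscape satisfies D Phi' = f and the analytic derivatives agree", {
  trip <- random_triples(20, seed = 31)
  for (i in seq_len(nrow(trip))) {
    p <- ratchet_params(trip$N[i], trip$mu[i], trip$sigma[i])
    expect_lt(landscape_consistency(p), 1e-6)
  }
  # analytic first/second derivatives against central differences
  p <- fix_clicking()
  x <- seq(0.05, 0.95, length.out = 19)
  h <- 1e-6
  num1 <- (potential_phi(x + h, p) - potential_phi(x - h, p)) / (2 * h)
  num2 <- (phi_prime(x + h, p) - phi_prime(x - h, p)) / (2 * h)
  expect_equal(phi_prime(x, p), num1, tolerance = 1e-7)
  expect_equal(phi_curvature(x, p), num2, tolerance = 1e-6)
})

test_that("landscape profile carries grid, exponents and boundary labels", {
  p <- fix_clicking()
  prof <- landscape_profile(p, n = 501)
  expect_identical(nrow(prof), 501L)
  expect_true(all(prof$x > 0 & prof$x < 1))
  expect_equal(prof$V, prof$x * (1 - prof$x) / p$N, tolerance = 1e-15)
  expect_equal(prof$D, prof$V / 2)
  d <- 1 - p$sigma * p$mu
  expect_equal(attr(prof, "A"), 2 * p$N * p$mu * (1 - p$sigma) / d)
  expect_equal(attr(prof, "B"), 2 * p$N * (1 - p$mu) / d)
  expect_identical(attr(prof, "boundary1"), "unadaptive")
})

test_that("boundary adaptiveness switches at the printed sigma threshold", {
  bc <- boundary_classification(fix_clicking())
  expect_identical(bc$x0, "adaptive")
  expect_identical(bc$x1, "unadaptive")
  expect_equal(bc$sigma_threshold, 1 / 1.98, tolerance = 1e-12)

  # 2 N mu < 1: threshold negative, x = 1 adaptive for every valid sigma
  for (sig in c(0.00005, 0.3, 0.9)) {
    bc2 <- boundary_classification(ratchet_params(50, 5e-6, sig))
    expect_identical(bc2$x1, "adaptive")
    expect_lt(bc2$sigma_threshold, 0)
  }
  # above the threshold x = 1 is adaptive even at high mutation
  expect_identical(boundary_classification(ratchet_params(50, 0.02, 0.9))$x1,
                   "adaptive")
})

test_that("landscape is monotone decreasing when both roots exceed 1", {
  # pick a parameter set mid-band between the double-root and
  # root-at-one curves, where both fixed points sit above 1
  N <- 50; mu <- 0.0101015
  th <- critical_thresholds(N, mu)
  p <- ratchet_params(N, mu, (th$sigma_double + th$sigma_unity) / 2)
  expect_identical(classify_regime(p)$regime, "I i")
  x <- seq(1e-4, 1 - 1e-4, length.out = 2001)
  expect_true(all(phi_prime(x, p) < 0))
})

test_that("stationary density is non-normalizable with exponent -1 at zero", {
  p <- fix_clicking()
  sd <- stationary_density(p)
  expect_false(sd$z_finite)
  expect_match(sd$divergence_reason, "exponent -1")
  expect_equal(sd$endpoint_exponents[["at0"]], -1)
  expect_gt(sd$endpoint_exponents[["at1"]], -1)

  # pointwise match to the literal density expression, up to one constant
  d <- 1 - p$sigma * p$mu
  lead <- (p$sigma * p$mu - 1 + 2 * p$N * p$mu * (1 - p$sigma)) / d
  literal <- exp(lead * log(1 - sd$x) - log(sd$x) +
                   (2 * p$N * (1 - p$mu) / d) *
                   log(1 - p$sigma + sd$x * p$sigma * (1 - p$mu)))
  ratio <- sd$values / literal
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
})

test_that("truncated stationary mass grows logarithmically without bound", {
  p <- fix_clicking()
  masses <- vapply(10^-(3:5), function(d) truncated_stationary_mass(p, d), 0)
  incr <- diff(masses)
  expect_true(all(incr > 0))
  # per-decade growth approaches log(10) times the limiting 1/x coefficient
  ab <- c(A = NA, B = 2 * p$N * (1 - p$mu) / (1 - p$sigma * p$mu))
  coef0 <- (1 - p$sigma)^ab[["B"]]
  expect_equal(incr[2], log(10) * coef0, tolerance = 0.05)
})
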