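test_that("alpha/beta parameterization matches direct arithmetic", {
  ab <- alpha_beta(fix_clicking())
  expect_equal(ab[["alpha"]], 4.851, tolerance = 1e-12)
  expect_equal(ab[["beta"]], 18.2476, tolerance = 1e-12)

  trip <- random_triples(50, seed = 41)
  for (i in seq_len(nrow(trip))) {
    p <- ratchet_params(trip$N[i], trip$mu[i], trip$sigma[i])
    ab <- alpha_beta(p)
    expect_gt(ab[["beta"]], 0)
    # beta = 4 * leading coefficient * constant term of the quadratic
    sf <- solve_fixed_points(p)
    expect_equal(ab[["beta"]], 4 * sf$coef[["a"]] * sf$coef[["c"]],
                 tolerance = 1e-12)
  }
})

test_that("fixed points solve the landscape quadratic", {
  p <- fix_clicking()
  sf <- solve_fixed_points(p)
  expect_equal(Re(sf$x1), 0.2657, tolerance = 5e-4 / 0.2657)
  expect_equal(Re(sf$x2), 0.7445, tolerance = 5e-4 / 0.7445)
  # polyroot oracle
  pr <- sort(Re(polyroot(c(sf$coef[["c"]], sf$coef[["b"]], sf$coef[["a"]]))))
  expect_equal(c(Re(sf$x1), Re(sf$x2)), pr, tolerance = 1e-10)

  # low-mutation fixture: one interior root, one far above 1
  sf2 <- solve_fixed_points(fix_low_mu())
  expect_true(Re(sf2$x1) > 0.49 && Re(sf2$x1) < 0.50)
  expect_gt(Re(sf2$x2), 100)

  # residual invariant across a random sweep, real or complex roots
  trip <- random_triples(200, seed = 43)
  for (i in seq_len(nrow(trip))) {
    pp <- ratchet_params(trip$N[i], trip$mu[i], trip$sigma[i])
    sfi <- solve_fixed_points(pp)
    scale <- max(1, abs(sfi$coef))
    for (r in c(sfi$x1, sfi$x2)) {
      res <- sfi$coef[["a"]] * r^2 + sfi$coef[["b"]] * r + sfi$coef[["c"]]
      expect_lt(Mod(res), 1e-10 * scale)
    }
  }
})

test_that("interior stationary points are zeros of f with alternating curvature", {
  p <- fix_clicking()
  rep <- classify_regime(p)
  x1 <- Re(rep$x1); x2 <- Re(rep$x2)
  expect_lt(abs(rate_f(x1, p)), 1e-10)
  expect_lt(abs(rate_f(x2, p)), 1e-10)
  expect_gt(phi_curvature(x1, p), 0)   # well (unadaptive)
  expect_lt(phi_curvature(x2, p), 0)   # barrier top (adaptive)
  expect_identical(rep$adaptiveness[["x1"]], "unadaptive")
  expect_identical(rep$adaptiveness[["x2"]], "adaptive")
})

test_that("regime classification reproduces the canonical cases", {
  expect_identical(classify_regime(fix_clicking())$regime, "I iv")
  expect_identical(classify_regime(fix_low_mu())$regime, "I iii")
  rep3 <- classify_regime(ratchet_params(50, 0.5, 0.51))
  expect_identical(rep3$regime, "III")
  expect_lt(rep3$discriminant, 0)
  expect_identical(rep3$adaptiveness[["x1"]], "not-applicable")
  # complex pair is conjugate
  expect_equal(rep3$x1, Conj(rep3$x2))
})

test_that("classification agrees with an independent root-position oracle", {
  trip <- random_triples(500, seed = 47)
  keep <- vapply(seq_len(nrow(trip)), function(i)
    away_from_bands(trip$N[i], trip$mu[i], trip$sigma[i]), TRUE)
  trip <- trip[keep, ]
  for (i in seq_len(nrow(trip))) {
    p <- ratchet_params(trip$N[i], trip$mu[i], trip$sigma[i])
    expect_identical(classify_regime(p)$regime,
                     brute_regime(trip$N[i], trip$mu[i], trip$sigma[i]))
  }
})

test_that("critical thresholds locate the double-root and root-at-one curves", {
  th <- critical_thresholds(50, 0.02)
  expect_equal(th$mu_breakpoints[["root_at_one_onset"]], 1 / 99)
  expect_equal(th$mu_breakpoints[["double_root_onset"]],
               2 / (99 + 2 * sqrt(2450)))
  expect_equal(th$sigma_unity, 1 / 1.98, tolerance = 1e-12)

  # on the double-root curve the discriminant vanishes
  for (mu in seq(0.02, 0.9, length.out = 25)) {
    th <- critical_thresholds(50, mu)
    expect_true(th$sigma_double_defined)
    ab <- alpha_beta(ratchet_params(50, mu, th$sigma_double))
    expect_lt(abs(ab[["alpha"]]^2 - ab[["beta"]]), 1e-6 * ab[["alpha"]]^2)
  }

  # below the onset the radicand is negative and the curve undefined
  th_lo <- critical_thresholds(50, 0.005)
  expect_false(th_lo$sigma_double_defined)
  expect_true(is.na(th_lo$sigma_double))

  # a root sits at x = 1 on the root-at-one curve
  th1 <- critical_thresholds(50, 0.03)
  sf <- solve_fixed_points(ratchet_params(50, 0.03, th1$sigma_unity))
  expect_lt(min(abs(Re(c(sf$x1, sf$x2)) - 1)), 1e-9)
})

test_that("regime atlas labels every valid cell exactly once", {
  atlas <- regime_atlas(50, seq(0.02, 0.9, length.out = 12),
                        seq(0.03, 0.95, length.out = 12))
  expect_true(all(atlas$sigma > atlas$mu))
  expect_true(all(nchar(atlas$regime) > 0))
  expect_identical(
    atlas$regime[atlas$mu == 0.02 & abs(atlas$sigma - 0.03) < 1e-12 |
                   FALSE][1],
    classify_regime(ratchet_params(50, 0.02, 0.03))$regime)

  # spot checks via the classifier
  spot <- regime_atlas(50, c(0.02, 0.5), c(0.05, 0.51))
  expect_identical(spot$regime[spot$mu == 0.02 & spot$sigma == 0.05], "I iv")
  expect_identical(spot$regime[spot$mu == 0.5 & spot$sigma == 0.51], "III")

  # the complex-roots band opens just above the double-root onset
  N <- 50
  mu0 <- 2 / (2 * N - 1 + 2 * sqrt(N * (N - 1)))
  mu <- mu0 * 1.02
  th <- critical_thresholds(N, mu)
  band <- regime_atlas(N, mu,
                       seq(mu * 1.01, th$sigma_double * 0.99,
                           length.out = 9))
  expect_true(any(band$regime == "III"))
})
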