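# Shared fixtures and oracles for the test suite.

# Canonical parameter sets: the finite-barrier clicking regime and the
# low-mutation infinite-barrier regime.
fix_clicking <- function() ratchet_params(50, 0.02, 0.05)
fix_low_mu <- function() ratchet_params(50, 0.000005, 0.00005)
fix_large_barrier <- function() ratchet_params(1000, 0.02, 0.05)

# Random valid parameter triples with sigma > mu, reproducible.
random_triples <- function(n, seed) {
  set.seed(seed)
  N <- sample(5:200, n, replace = TRUE)
  mu <- stats::runif(n, 0.001, 0.6)
  sigma <- stats::runif(n, mu + 1e-3, 0.99)
  data.frame(N = N, mu = mu, sigma = sigma)
}

# Independent root-position classifier: builds the fixed-point quadratic
# from its raw coefficients and uses base R's polyroot(), no shared code
# with classify_regime().
brute_regime <- function(N, mu, sigma, tol = 1e-9) {
  a <- 2 * sigma * (1 - mu) * (N - 1)
  b <- 2 * N * (mu - sigma) + 3 * sigma - sigma * mu - 2
  cc <- 1 - sigma
  disc <- b^2 - 4 * a * cc
  if (abs(disc) <= tol * max(b^2, 1)) {
    r <- -b / (2 * a)
    return(if (abs(r - 1) <= tol) "II ii" else if (r > 1) "II i"
           else if (r > tol && r < 1) "II iii" else "boundary-case")
  }
  if (disc < 0) return("III")
  roots <- sort(Re(polyroot(c(cc, b, a))))
  x1 <- roots[1]; x2 <- roots[2]
  if (x1 < -tol || x2 < -tol) return("I vi-impossible")
  if (abs(x1 - 1) <= tol && x2 > 1 + tol) return("I ii")
  if (abs(x1) <= tol && x2 > 1 + tol) return("I v")
  if (min(abs(c(x1, x2))) <= tol || min(abs(c(x1, x2) - 1)) <= tol)
    return("boundary-case")
  if (x1 > 1) "I i" else if (x2 > 1) "I iii" else "I iv"
}

# Filter out triples sitting inside the tolerance bands of the
# classification (near the double-root curve or a root near 0/1).
away_from_bands <- function(N, mu, sigma, band = 1e-6) {
  a <- 2 * sigma * (1 - mu) * (N - 1)
  b <- 2 * N * (mu - sigma) + 3 * sigma - sigma * mu - 2
  cc <- 1 - sigma
  disc <- b^2 - 4 * a * cc
  if (abs(disc) <= band * max(b^2, 1)) return(FALSE)
  if (disc < 0) return(TRUE)
  roots <- sort(Re(polyroot(c(cc, b, a))))
  all(abs(roots) > band) && all(abs(roots - 1) > band)
}
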