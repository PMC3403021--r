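# Diffusion-approximation ingredients (drift M, variance V, diffusion D,
# directional transition rate f) and the closed-form adaptive landscape Phi,
# with boundary classification and the (non-)normalizability certificate for
# the stationary density.

# Selection-mutation denominator g(x) = 1 - sigma + sigma (1 - mu) x,
# bounded below by 1 - sigma > 0 on [0, 1].
.g <- function(x, params) 1 - params$sigma + params$sigma * (1 - params$mu) * x

# Landscape exponents: Phi(x) = A log(1-x) - eps*log(x(1-x)) + B log g(x).
.landscape_exponents <- function(params) {
  with(params, {
    d <- 1 - sigma * mu
    c(A = 2 * N * mu * (1 - sigma) / d, B = 2 * N * (1 - mu) / d)
  })
}

#' Drift, variance, diffusion and directional transition rate
#'
#' Ingredients of the diffusion approximation to the ratchet chain on the
#' allele-frequency interval.  `drift_M` is the expected one-generation
#' frequency change from mutation and selection,
#' \deqn{M(x) = \frac{x\left[(\sigma-\mu) - \sigma(1-\mu)x\right]}
#'                   {1-\sigma+\sigma(1-\mu)x},}
#' identical to `deterministic_map(x) - x`.  `variance_V` is the binomial
#' sampling variance \eqn{V(x) = x(1-x)/N}, `diffusion_D` is `V/2`, and
#' `rate_f` is the directional transition rate
#' \eqn{f(x) = M(x) - \epsilon D'(x)} with \eqn{D'(x) = (1-2x)/(2N)}.
#' The adaptive landscape is the integral of `f / D` (see
#' [potential_phi()]); its stationary points are the zeros of `f`.
#'
#' @param x Frequencies in \[0, 1\] (for `rate_f`, typically interior).
#' @param params A [ratchet_params()] object.
#' @return Numeric vector of the same length as `x`.  Units: frequency per
#'   generation for `M` and `f`; squared frequency per generation for `V`
#'   and `D`.
#' @examples
#' p <- ratchet_params(50, 0.02, 0.05)
#' drift_M(1, p)          # -mu (1 - sigma) / (1 - sigma mu)
#' variance_V(0.5, p)     # 0.005
#' @export
drift_M <- function(x, params) {
  params <- .check_params(params)
  x * ((params$sigma - params$mu) - params$sigma * (1 - params$mu) * x) /
    .g(x, params)
}

#' @rdname drift_M
#' @export
variance_V <- function(x, params) {
  params <- .check_params(params)
  x * (1 - x) / params$N
}

#' @rdname drift_M
#' @export
diffusion_D <- function(x, params) variance_V(x, params) / 2

#' @rdname drift_M
#' @export
rate_f <- function(x, params) {
  params <- .check_params(params)
  drift_M(x, params) - params$epsilon * (1 - 2 * x) / (2 * params$N)
}

#' Adaptive landscape and its derivatives
#'
#' The adaptive landscape is the potential whose gradient reproduces the
#' directional transition rate, \eqn{D(x)\,\Phi'(x) = f(x)}.  Integrating
#' `f / D` in closed form gives
#' \deqn{\Phi(x) = A\ln(1-x) - \epsilon\ln\!\big(x(1-x)\big) + B\ln\!\big(1-\sigma+x\sigma(1-\mu)\big),}
#' with exponents \eqn{A = 2N\mu(1-\sigma)/(1-\sigma\mu)} and
#' \eqn{B = 2N(1-\mu)/(1-\sigma\mu)} (both positive).  The additive constant
#' is fixed as written: no extra offset is applied, and all physical uses are
#' differences.  Maxima of \eqn{\Phi} are adaptive (locally stable) states,
#' minima unadaptive; \eqn{\Phi \to +\infty} at `x = 0` always, while the
#' sign of the divergence at `x = 1` depends on `A - 1` (see
#' [boundary_classification()]).
#'
#' `phi_prime` and `phi_curvature` are the analytic first and second
#' derivatives,
#' \eqn{\Phi'(x) = (\epsilon - A)/(1-x) - \epsilon/x + B\sigma(1-\mu)/g(x)}
#' and its derivative, used by the fixed-point classifier and the
#' saddle-point click-time formula.
#'
#' @param x Frequencies strictly inside (0, 1); the endpoints are
#'   logarithmic singularities and are refused.
#' @param params A [ratchet_params()] object.
#' @return Numeric vector of landscape values (dimensionless) or derivative
#'   values.
#' @examples
#' p <- ratchet_params(50, 0.02, 0.05)
#' potential_phi(c(1e-4, 1e-3, 1e-2), p)  # decreasing: +Inf divergence at 0
#' @export
potential_phi <- function(x, params) {
  params <- .check_params(params)
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 1))
    stop("`x` must lie strictly inside (0, 1): the landscape is singular at the endpoints",
         call. = FALSE)
  ab <- .landscape_exponents(params)
  ab[["A"]] * log1p(-x) - params$epsilon * (log(x) + log1p(-x)) +
    ab[["B"]] * log(.g(x, params))
}

#' @rdname potential_phi
#' @export
phi_prime <- function(x, params) {
  params <- .check_params(params)
  if (any(x <= 0) || any(x >= 1))
    stop("`x` must lie strictly inside (0, 1)", call. = FALSE)
  ab <- .landscape_exponents(params)
  eps <- params$epsilon
  (eps - ab[["A"]]) / (1 - x) - eps / x +
    ab[["B"]] * params$sigma * (1 - params$mu) / .g(x, params)
}

#' @rdname potential_phi
#' @export
phi_curvature <- function(x, params) {
  params <- .check_params(params)
  if (any(x <= 0) || any(x >= 1))
    stop("`x` must lie strictly inside (0, 1)", call. = FALSE)
  ab <- .landscape_exponents(params)
  eps <- params$epsilon
  (eps - ab[["A"]]) / (1 - x)^2 + eps / x^2 -
    ab[["B"]] * (params$sigma * (1 - params$mu))^2 / .g(x, params)^2
}

#' Gridded landscape profile
#'
#' Evaluates `M`, `V`, `D`, `f` and `Phi` on an open-interval grid
#' `seq(delta, 1 - delta, length.out = n)` and attaches the landscape
#' exponents and boundary-divergence labels as attributes.  The clipping
#' `delta` defaults to `min(1e-6, 1/(10 N))`; the landscape is never
#' evaluated at 0 or 1.
#'
#' @param params A [ratchet_params()] object.
#' @param n Number of grid points (default 2001).
#' @param delta Endpoint clipping; `NULL` for the default.
#' @return A `data.frame` (class `"ratchet_landscape"`) with columns `x`,
#'   `M`, `V`, `D`, `f`, `phi`, and attributes `A`, `B`, `boundary0`,
#'   `boundary1`, `delta`.
#' @export
landscape_profile <- function(params, n = 2001, delta = NULL) {
  params <- .check_params(params)
  if (is.null(delta)) delta <- min(1e-6, 1 / (10 * params$N))
  if (delta <= 0 || delta >= 0.5) stop("`delta` must lie in (0, 0.5)",
                                       call. = FALSE)
  x <- seq(delta, 1 - delta, length.out = n)
  out <- data.frame(
    x = x,
    M = drift_M(x, params),
    V = variance_V(x, params),
    D = diffusion_D(x, params),
    f = rate_f(x, params),
    phi = potential_phi(x, params)
  )
  ab <- .landscape_exponents(params)
  bc <- boundary_classification(params)
  attr(out, "A") <- ab[["A"]]
  attr(out, "B") <- ab[["B"]]
  attr(out, "boundary0") <- bc$x0
  attr(out, "boundary1") <- bc$x1
  attr(out, "delta") <- delta
  class(out) <- c("ratchet_landscape", "data.frame")
  out
}

#' Adaptiveness of the boundary frequencies
#'
#' Near `x = 0` the landscape behaves like \eqn{-\epsilon\ln x \to +\infty},
#' so the lost-fittest-class boundary is always adaptive (a potential peak;
#' this is the absorbing state).  Near `x = 1` the leading term is
#' \eqn{(A-\epsilon)\ln(1-x)}: for `A > 1` (with `epsilon = 1`) the landscape
#' diverges to \eqn{-\infty} and `x = 1` is unadaptive, for `A < 1` to
#' \eqn{+\infty} and `x = 1` is adaptive.  In terms of the selection
#' coefficient the divide is
#' \eqn{\sigma^\dagger = (2N\mu - 1)/\big((2N-1)\mu\big)}: `x = 1` is
#' unadaptive for \eqn{\sigma < \sigma^\dagger} and adaptive above it (for
#' \eqn{2N\mu < 1} the threshold is negative, so `x = 1` is adaptive for all
#' valid `sigma`).
#'
#' @param params A [ratchet_params()] object.
#' @param tol Width of the boundary-case band on `A - epsilon`.
#' @return List with labels `x0`, `x1` (each `"adaptive"`, `"unadaptive"` or
#'   `"boundary-case"`), the threshold `sigma_threshold`, and the exponent
#'   `A`.
#' @examples
#' boundary_classification(ratchet_params(50, 0.02, 0.05))  # x=1 unadaptive
#' @export
boundary_classification <- function(params, tol = 1e-9) {
  params <- .check_params(params)
  ab <- .landscape_exponents(params)
  lead1 <- ab[["A"]] - params$epsilon   # coefficient of log(1-x) as x -> 1
  x1 <- if (abs(lead1) <= tol) "boundary-case"
        else if (lead1 > 0) "unadaptive" else "adaptive"
  list(
    x0 = "adaptive",
    x1 = x1,
    sigma_threshold = (2 * params$N * params$mu - 1) /
      ((2 * params$N - 1) * params$mu),
    A = ab[["A"]]
  )
}

#' Unnormalized stationary density and its divergence certificate
#'
#' The formal stationary density of the diffusion is the Boltzmann-Gibbs
#' form \eqn{\rho(x) \propto e^{\Phi(x)/\epsilon}}.  Its normalizing
#' constant is never finite here: near `x = 0` the density behaves like
#' \eqn{x^{-1}} (exponent \eqn{-1}), a logarithmically divergent integral.
#' That non-normalizability is the analytic signature of the absorbing
#' boundary: probability accumulates at frequency 0 instead of settling
#' into a proper stationary law.  The `x = 1` endpoint has exponent
#' \eqn{A - 1 > -1} and is integrable.
#'
#' @param params A [ratchet_params()] object.
#' @param grid Frequencies in (0, 1) at which to evaluate; `NULL` for the
#'   default landscape grid.
#' @param log_offset Constant subtracted from `Phi/epsilon` before
#'   exponentiating (the density is only defined up to a constant; use the
#'   maximum of `Phi` to avoid overflow at large `N`).
#' @return List with `x`, `values` (`exp(Phi/epsilon - log_offset)`),
#'   `log_values`, `z_finite` (always `FALSE`), `divergence_reason`, and
#'   `endpoint_exponents` (at 0 and at 1).
#' @export
stationary_density <- function(params, grid = NULL, log_offset = 0) {
  params <- .check_params(params)
  if (is.null(grid)) {
    delta <- min(1e-6, 1 / (10 * params$N))
    grid <- seq(delta, 1 - delta, length.out = 1001)
  }
  lv <- potential_phi(grid, params) / params$epsilon - log_offset
  ab <- .landscape_exponents(params)
  list(
    x = grid,
    values = exp(lv),
    log_values = lv,
    z_finite = FALSE,
    divergence_reason = paste0(
      "endpoint exponent -1 at x = 0 (factor 1/x in exp(Phi)): ",
      "the normalizing integral diverges logarithmically, so no proper ",
      "stationary distribution exists (absorbing boundary)"),
    endpoint_exponents = c(at0 = -1, at1 = ab[["A"]] - 1)
  )
}

#' Mass of the truncated stationary density
#'
#' Integrates `exp(Phi/epsilon)` over `(delta, 1 - delta)`.  As `delta`
#' shrinks, the mass grows without bound, by approximately
#' `log(10) * (1 - sigma)^B` per decade of `delta` (the limiting coefficient
#' of the `1/x` singularity), which is the numeric witness of the divergent
#' normalizing constant.
#'
#' @param params A [ratchet_params()] object.
#' @param delta Truncation distance from the endpoints, in (0, 0.5).
#' @param log_offset Constant subtracted from `Phi/epsilon` (see
#'   [stationary_density()]).
#' @return The truncated integral (a single number).
#' @export
truncated_stationary_mass <- function(params, delta, log_offset = 0) {
  params <- .check_params(params)
  if (delta <= 0 || delta >= 0.5) stop("`delta` must lie in (0, 0.5)",
                                       call. = FALSE)
  f <- function(x) exp(potential_phi(x, params) / params$epsilon - log_offset)
  # split at midpoint: the integrand is singularity-free inside but steep
  # near both ends
  i1 <- stats::integrate(f, delta, 0.5, rel.tol = 1e-10)
  i2 <- stats::integrate(f, 0.5, 1 - delta, rel.tol = 1e-10)
  i1$value + i2$value
}

#' Consistency of the closed-form landscape with its defining relation
#'
#' Checks \eqn{D(x)\,\Phi'(x) = f(x)} on a grid, differentiating the
#' closed-form `Phi` numerically by centered differences.  The step is
#' proportional to the distance from the nearest endpoint
#' (`h = 1e-5 * min(x, 1 - x)`), which keeps both the truncation error and
#' the cancellation error of the difference quotient far below the reported
#' deviations even next to the logarithmic singularities.
#'
#' @param params A [ratchet_params()] object.
#' @param n Grid size (default 2001).
#' @param delta Endpoint clipping; `NULL` for the [landscape_profile()]
#'   default.
#' @return Maximum absolute deviation `|D * dPhi/dx - f|` over the grid.
#' @export
landscape_consistency <- function(params, n = 2001, delta = NULL) {
  params <- .check_params(params)
  if (is.null(delta)) delta <- min(1e-6, 1 / (10 * params$N))
  x <- seq(delta, 1 - delta, length.out = n)
  h <- 1e-5 * pmin(x, 1 - x)
  dphi <- (potential_phi(x + h, params) - potential_phi(x - h, params)) /
    (2 * h)
  max(abs(diffusion_D(x, params) * dphi - rate_f(x, params)))
}
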