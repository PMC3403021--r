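# Stationary points of the adaptive landscape: the alpha/beta
# parameterization of the quadratic Phi'(x) = 0, the full regime taxonomy
# over the (mu, sigma) plane, and the critical threshold curves.

.check_eps1 <- function(params) {
  if (params$epsilon != 1)
    stop("the fixed-point taxonomy assumes epsilon = 1", call. = FALSE)
  params
}

#' Quadratic parameterization of the landscape fixed points
#'
#' The stationary points of the adaptive landscape solve
#' \deqn{2\sigma(1-\mu)(N-1)\,x^2 + \big(2N(\mu-\sigma)+3\sigma-\sigma\mu-2\big)\,x + (1-\sigma) = 0,}
#' conveniently written through
#' \deqn{\alpha = 2 - 3\sigma + \sigma\mu + 2N\sigma - 2N\mu, \qquad
#'       \beta = 8\sigma(1-\mu)(N-1)(1-\sigma),}
#' so that the roots are \eqn{x_{1,2} = (\alpha \mp \sqrt{\alpha^2-\beta}) /
#' (4\sigma(1-\mu)(N-1))}.  `beta` is positive for all valid parameters and
#' equals four times the product of the quadratic's leading coefficient and
#' constant term; the discriminant \eqn{\alpha^2 - \beta} decides between
#' real and complex fixed points.
#'
#' @param params A [ratchet_params()] object (with `epsilon = 1`).
#' @return Named numeric vector `c(alpha, beta)`.
#' @examples
#' alpha_beta(ratchet_params(50, 0.02, 0.05))  # alpha 4.851, beta 18.2476
#' @export
alpha_beta <- function(params) {
  params <- .check_eps1(.check_params(params))
  with(params, c(
    alpha = 2 - 3 * sigma + sigma * mu + 2 * N * sigma - 2 * N * mu,
    beta = 8 * sigma * (1 - mu) * (N - 1) * (1 - sigma)
  ))
}

#' Fixed points of the adaptive landscape
#'
#' Solves the landscape quadratic (see [alpha_beta()]).  When the
#' discriminant is negative the roots form a complex-conjugate pair; they
#' are returned as complex numbers ordered so that `x1` carries the
#' negative imaginary part (for real roots, `x1 <= x2`).
#'
#' @param params A [ratchet_params()] object (with `epsilon = 1`).
#' @return List with `alpha`, `beta`, `discriminant`, complex roots `x1`,
#'   `x2`, and the quadratic coefficients `coef = c(a, b, c)`.
#' @export
solve_fixed_points <- function(params) {
  params <- .check_eps1(.check_params(params))
  ab <- alpha_beta(params)
  disc <- ab[["alpha"]]^2 - ab[["beta"]]
  denom <- 4 * params$sigma * (1 - params$mu) * (params$N - 1)
  if (disc >= 0) {
    r <- sqrt(disc)
    if (ab[["alpha"]] > 0) {
      # Vieta form for the smaller root avoids cancellation when the
      # discriminant is close to alpha^2 (beta << alpha^2)
      b2 <- (ab[["alpha"]] + r) / denom
      b1 <- (1 - params$sigma) / (denom / 2 * b2)
    } else {
      b1 <- (ab[["alpha"]] - r) / denom
      b2 <- (ab[["alpha"]] + r) / denom
    }
    x1 <- complex(real = b1, imaginary = 0)
    x2 <- complex(real = b2, imaginary = 0)
  } else {
    r <- sqrt(-disc)
    x1 <- complex(real = ab[["alpha"]] / denom, imaginary = -r / denom)
    x2 <- Conj(x1)
  }
  list(
    alpha = ab[["alpha"]], beta = ab[["beta"]], discriminant = disc,
    x1 = x1, x2 = x2,
    coef = c(a = 2 * params$sigma * (1 - params$mu) * (params$N - 1),
             b = 2 * params$N * (params$mu - params$sigma) +
               3 * params$sigma - params$sigma * params$mu - 2,
             c = 1 - params$sigma)
  )
}

#' Classify the fixed-point regime of a parameter set
#'
#' Assigns each parameter triple its place in the landscape taxonomy,
#' primarily from the numerically computed roots (discriminant sign, then
#' the position of each real root relative to 0 and 1 within `tol`):
#'
#' * `I i` .. `I iv`: two distinct real roots, labelled by position
#'   (`I i`: both above 1; `I ii`: lower root at 1; `I iii`: one interior,
#'   one above 1; `I iv`: both interior — the clicking regime with an
#'   interior well at `x1` and peak at `x2`);
#' * `I v` (lower root at 0) cannot occur for `sigma < 1`, and negative
#'   roots are reported as `I vi-impossible`;
#' * `II i` .. `II iii`: discriminant within `tol * alpha^2` of zero
#'   (double root), labelled by its position;
#' * `III`: negative discriminant, complex pair;
#' * `boundary-case`: a root within `tol` of 0 or 1 in a configuration not
#'   covered above.
#'
#' Adaptiveness is measured by the landscape itself: `x = 0` is adaptive
#' (always a \eqn{+\infty} peak for `sigma < 1`), `x = 1` follows
#' [boundary_classification()], and an interior root is unadaptive when it
#' is a minimum of the landscape (positive curvature) and adaptive when it
#' is a maximum.
#'
#' @param params A [ratchet_params()] object (with `epsilon = 1`).
#' @param tol Relative tolerance for the discriminant test and absolute
#'   tolerance for root-boundary comparisons.
#' @return An object of class `"fixed_point_report"`: list with `params`,
#'   `alpha`, `beta`, `discriminant`, `x1`, `x2`, `regime`, `adaptiveness`
#'   (named labels for `x=0`, `x=1`, `x1`, `x2`) and `tol`.
#' @examples
#' classify_regime(ratchet_params(50, 0.02, 0.05))$regime   # "I iv"
#' @export
classify_regime <- function(params, tol = 1e-9) {
  params <- .check_eps1(.check_params(params))
  sf <- solve_fixed_points(params)
  a2 <- max(sf$alpha^2, .Machine$double.eps)
  near <- function(u, v) abs(u - v) <= tol
  if (abs(sf$discriminant) <= tol * a2) {
    r <- sf$alpha / (4 * params$sigma * (1 - params$mu) * (params$N - 1))
    regime <- if (near(r, 1)) "II ii"
              else if (r > 1) "II i"
              else if (r > tol && r < 1) "II iii"
              else "boundary-case"
  } else if (sf$discriminant < 0) {
    regime <- "III"
  } else {
    x1 <- Re(sf$x1); x2 <- Re(sf$x2)
    regime <-
      if (x1 < -tol || x2 < -tol) "I vi-impossible"
      else if (near(x1, 1) && x2 > 1 + tol) "I ii"
      else if (near(x1, 0) && x2 > 1 + tol) "I v"
      else if (near(x1, 0) || near(x1, 1) || near(x2, 0) || near(x2, 1))
        "boundary-case"
      else if (x1 > 1) "I i"
      else if (x2 > 1) "I iii"
      else "I iv"
  }
  root_label <- function(r) {
    if (abs(Im(r)) > 0) return("not-applicable")
    x <- Re(r)
    if (x <= tol || x >= 1 - tol) return("not-applicable")
    if (phi_curvature(x, params) > 0) "unadaptive" else "adaptive"
  }
  adapt <- c(
    "x=0" = "adaptive",
    "x=1" = boundary_classification(params)$x1,
    "x1" = root_label(sf$x1),
    "x2" = root_label(sf$x2)
  )
  structure(
    list(params = params, alpha = sf$alpha, beta = sf$beta,
         discriminant = sf$discriminant, x1 = sf$x1, x2 = sf$x2,
         regime = regime, adaptiveness = adapt, tol = tol),
    class = "fixed_point_report"
  )
}

#' @export
print.fixed_point_report <- function(x, ...) {
  fmt <- function(z) {
    if (Im(z) == 0) sprintf("%.6g", Re(z))
    else sprintf("%.6g %+.6gi", Re(z), Im(z))
  }
  cat(sprintf("<fixed_point_report> regime %s\n", x$regime))
  cat(sprintf("  alpha = %.6g, beta = %.6g, discriminant = %.6g\n",
              x$alpha, x$beta, x$discriminant))
  cat(sprintf("  x1 = %s, x2 = %s\n", fmt(x$x1), fmt(x$x2)))
  cat("  adaptiveness:",
      paste(names(x$adaptiveness), x$adaptiveness, sep = ": ",
            collapse = ", "), "\n")
  invisible(x)
}

#' Critical curves of the regime taxonomy
#'
#' Returns the mutation-rate breakpoints that organize the parameter plane
#' for a given `N`,
#' `1/(2N-1)`, `2/(2N-1+2*sqrt(N(N-1)))`, `(2N-1)/(4N(N-1))` and
#' `(2N-1)/(4N-3)`, together with the two sigma threshold curves at the
#' given `mu`:
#'
#' * `sigma_double(mu)`: the double-root curve on which the discriminant
#'   \eqn{\alpha^2 - \beta} vanishes,
#'   \deqn{\sigma_2(\mu) = \frac{2+2\mu-10N\mu+4N^2\mu+2N\mu^2 +
#'     4(1-\mu)\sqrt{N(N-1)\big((2N-1)\mu-1\big)}}{(\mu-2N+1)^2},}
#'   defined only when \eqn{(2N-1)\mu \ge 1} (otherwise the radicand is
#'   negative and the discriminant is positive for all valid `sigma`);
#' * `sigma_unity(mu) = (2N mu - 1) / ((2N - 1) mu)`: the curve on which a
#'   root sits at `x = 1`, which is also the boundary-adaptiveness divide of
#'   [boundary_classification()].
#'
#' @param N Population size (integer, at least 2).
#' @param mu Mutation probability in (0, 1).
#' @return List with `mu_breakpoints` (named numeric vector),
#'   `sigma_double` (`NA` when undefined), `sigma_double_defined`, and
#'   `sigma_unity`.
#' @export
critical_thresholds <- function(N, mu) {
  if (length(N) != 1L || N < 2 || N != round(N))
    stop("`N` must be a single integer >= 2", call. = FALSE)
  if (length(mu) != 1L || mu <= 0 || mu >= 1)
    stop("`mu` must lie in (0, 1)", call. = FALSE)
  breaks <- c(
    root_at_one_onset = 1 / (2 * N - 1),
    double_root_onset = 2 / (2 * N - 1 + 2 * sqrt(N * (N - 1))),
    interior_double_onset = (2 * N - 1) / (4 * N * (N - 1)),
    interior_double_offset = (2 * N - 1) / (4 * N - 3)
  )
  radicand <- N * (N - 1) * ((2 * N - 1) * mu - 1)
  defined <- radicand >= 0
  sigma_double <- if (defined) {
    (2 + 2 * mu - 10 * N * mu + 4 * N^2 * mu + 2 * N * mu^2 +
       4 * (1 - mu) * sqrt(radicand)) / (mu - 2 * N + 1)^2
  } else NA_real_
  list(
    mu_breakpoints = breaks,
    sigma_double = sigma_double,
    sigma_double_defined = defined,
    sigma_unity = (2 * N * mu - 1) / ((2 * N - 1) * mu)
  )
}

#' Regime atlas over a parameter grid
#'
#' Classifies every cell of a `(mu, sigma)` grid (restricted to
#' `sigma > mu`) and tabulates the regime label, the roots and the
#' discriminant, reproducing the parameter-plane atlas of the taxonomy.
#'
#' @param N Population size.
#' @param mu_grid,sigma_grid Numeric vectors inside (0, 1).
#' @param tol Tolerance passed to [classify_regime()].
#' @return A `data.frame` with columns `mu`, `sigma`, `regime`, `x1_re`,
#'   `x1_im`, `x2_re`, `x2_im`, `discriminant`.
#' @export
regime_atlas <- function(N, mu_grid, sigma_grid, tol = 1e-9) {
  cells <- expand.grid(mu = mu_grid, sigma = sigma_grid,
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[cells$sigma > cells$mu, , drop = FALSE]
  if (!nrow(cells)) stop("no grid cells satisfy sigma > mu", call. = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    rep <- classify_regime(
      ratchet_params(N, cells$mu[i], cells$sigma[i], strict = FALSE),
      tol = tol)
    data.frame(mu = cells$mu[i], sigma = cells$sigma[i],
               regime = rep$regime,
               x1_re = Re(rep$x1), x1_im = Im(rep$x1),
               x2_re = Re(rep$x2), x2_im = Im(rep$x2),
               discriminant = rep$discriminant)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
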