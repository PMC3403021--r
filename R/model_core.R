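# Deterministic core of the two-allele ratchet model: parameter record,
# the drift-free mutation-selection recursion, and its fixed points.

#' Validated parameter set for the two-allele ratchet model
#'
#' Bundles the haploid population size `N`, the per-generation deleterious
#' mutation probability `mu` (wild-type allele A mutates to a), the selection
#' coefficient `sigma` (the mutant allele a has relative viability
#' `1 - sigma`) and the landscape scale constant `epsilon` into a validated
#' record that every other function in the package consumes.
#'
#' Domain checks: `N` must be a single integer with `N >= 2` (the chain and
#' the fixed-point quadratic both degenerate at `N = 1`); `mu` and `sigma`
#' must lie strictly inside (0, 1); `epsilon` must be positive.  The value
#' `sigma = 1` is refused everywhere because the one-generation map is 0/0 at
#' frequency 0 in that limit.
#'
#' With `strict = TRUE` the ordering `sigma > mu` is additionally enforced:
#' only then does the interior mutation-selection equilibrium
#' \eqn{(\sigma-\mu)/(\sigma(1-\mu))} lie in (0, 1].  The command-line
#' interface validates strictly by default; the library constructor is
#' permissive so that degenerate limits remain usable.
#'
#' @param N Haploid population size (single integer, at least 2).
#' @param mu Deleterious mutation probability per generation, in (0, 1).
#' @param sigma Selection coefficient against the mutant allele, in (0, 1).
#' @param epsilon Landscape scale constant (default 1).  It multiplies the
#'   drift-derivative term in the directional transition rate
#'   `f = M - epsilon * D'` and scales the stationary density
#'   `exp(Phi / epsilon)`.  The fixed-point taxonomy assumes `epsilon = 1`.
#' @param strict Logical; additionally require `sigma > mu`.
#' @return An object of class `"ratchet_params"`: a list with fields `N`,
#'   `mu`, `sigma`, `epsilon` and `strict`.
#' @examples
#' ratchet_params(50, 0.02, 0.05, strict = TRUE)
#' @export
ratchet_params <- function(N, mu, sigma, epsilon = 1, strict = FALSE) {
  if (length(N) != 1L || !is.numeric(N) || !is.finite(N) || N != round(N))
    stop("`N` must be a single integer", call. = FALSE)
  N <- as.integer(N)
  if (N < 2L)
    stop("`N` must be at least 2: the model assumes N > 1", call. = FALSE)
  for (nm in c("mu", "sigma")) {
    val <- get(nm)
    if (length(val) != 1L || !is.numeric(val) || !is.finite(val))
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    if (val <= 0 || val >= 1)
      stop(sprintf("`%s` must lie strictly inside (0, 1); got %g", nm, val),
           call. = FALSE)
  }
  if (length(epsilon) != 1L || !is.numeric(epsilon) || !is.finite(epsilon) ||
      epsilon <= 0)
    stop("`epsilon` must be a single positive number", call. = FALSE)
  if (isTRUE(strict) && sigma <= mu)
    stop(sprintf(paste0("strict validation requires sigma > mu ",
                        "(selection stronger than mutation); ",
                        "got sigma = %g <= mu = %g"), sigma, mu),
         call. = FALSE)
  structure(
    list(N = N, mu = mu, sigma = sigma, epsilon = epsilon,
         strict = isTRUE(strict)),
    class = "ratchet_params"
  )
}

#' @export
print.ratchet_params <- function(x, ...) {
  cat(sprintf(
    "<ratchet_params> N = %d, mu = %g, sigma = %g, epsilon = %g%s\n",
    x$N, x$mu, x$sigma, x$epsilon,
    if (x$strict) " (strict)" else ""))
  invisible(x)
}

.check_params <- function(params) {
  if (!inherits(params, "ratchet_params"))
    stop("`params` must be a `ratchet_params` object; see ?ratchet_params",
         call. = FALSE)
  params
}

#' One-generation deterministic mutation-selection map
#'
#' Expected frequency of the wild-type allele A in the next generation, given
#' its current frequency `p`, ignoring random drift:
#' \deqn{p' = \frac{(1-\mu)\,p}{1 - \sigma + \sigma (1-\mu)\, p}.}
#' The map is monotone non-decreasing on \[0, 1\] and fixes 0; for
#' `sigma > mu` iterates from any interior start converge to the
#' mutation-selection equilibrium \eqn{(\sigma-\mu)/(\sigma(1-\mu))}.
#'
#' Arguments are permissive (`mu`, `sigma` may be 0) so that the neutral and
#' mutation-free limits remain evaluable; `sigma = 1` is refused because the
#' expression is 0/0 at `p = 0`.
#'
#' @param p Frequency (or vector of frequencies) of allele A, in \[0, 1\].
#' @param mu Mutation probability, in \[0, 1).
#' @param sigma Selection coefficient, in \[0, 1).
#' @return Frequencies in \[0, 1\], same length as `p`.
#' @examples
#' deterministic_map(0.5, 0, 0)          # both forces off: identity
#' deterministic_map(1, 0.5, 0.5)        # 2/3
#' @export
deterministic_map <- function(p, mu, sigma) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("`p` must lie in [0, 1]", call. = FALSE)
  if (mu < 0 || mu >= 1) stop("`mu` must lie in [0, 1)", call. = FALSE)
  if (sigma < 0 || sigma >= 1)
    stop("`sigma` must lie in [0, 1): at sigma = 1 the map is undefined (0/0 at p = 0)",
         call. = FALSE)
  (1 - mu) * p / (1 - sigma + sigma * (1 - mu) * p)
}

#' Fixed points of the deterministic mutation-selection recursion
#'
#' The drift-free map has the absorbing fixed point 0 and the interior
#' mutation-selection balance \eqn{\hat p = (\sigma-\mu)/(\sigma(1-\mu))},
#' which lies in (0, 1\] exactly when `sigma > mu`.  When `sigma <= mu` the
#' second value is still returned (it is the algebraic root) but a warning is
#' raised and the `"interior_valid"` attribute is set to `FALSE`.
#'
#' @param params A [ratchet_params()] object.
#' @return Numeric vector `c(0, p2)` with attribute `interior_valid`.
#' @examples
#' deterministic_fixed_points(ratchet_params(50, 0.25, 0.5))  # c(0, 2/3)
#' @export
deterministic_fixed_points <- function(params) {
  params <- .check_params(params)
  p2 <- (params$sigma - params$mu) / (params$sigma * (1 - params$mu))
  ok <- params$sigma > params$mu
  if (!ok)
    warning(sprintf(paste0("sigma = %g <= mu = %g: the interior balance ",
                           "point %g is not in (0, 1]"),
                    params$sigma, params$mu, p2), call. = FALSE)
  structure(c(0, p2), interior_valid = ok)
}
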