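# The discrete Wright-Fisher ratchet chain: one-generation transition
# matrix with its absorbing/transient partition, distribution propagation,
# quasi-stationary spectrum, exact mean absorption times, and Monte-Carlo
# click-time sampling.

#' One-generation transition matrix of the ratchet chain
#'
#' The chain tracks the count `n` of wild-type (A) alleles in a population of
#' fixed size `N`.  Conditional on the current count `n`, the next count is
#' binomial with `N` trials and success probability equal to the
#' deterministic mutation-selection map evaluated at `n / N`
#' ([deterministic_map()]).  State 0 (fittest class lost) is absorbing: its
#' row is exactly `(1, 0, ..., 0)`.
#'
#' The matrix is stored row-stochastically: `P[n + 1, m + 1]` is the
#' probability of moving from `n` copies to `m` copies, and distributions are
#' propagated on the right (`dist %*% P`).  The transient partition is
#' extracted as `v` (one-step absorption probabilities from states
#' `1, ..., N` into state 0) and `w` (the `N x N` transient-to-transient
#' block), so that each row of `w` sums to `1 - v[n]`.
#'
#' Binomial masses come from `stats::dbinom`, which works in log-gamma space
#' internally and is overflow-safe for `N` well beyond 2000.  A row is
#' renormalized (with a message) only if its sum deviates from 1 by more than
#' 1e-12, which does not occur for double-precision `dbinom` rows.
#'
#' @param params A [ratchet_params()] object; `sigma < 1` is guaranteed by
#'   its validation.
#' @return An object of class `"ratchet_tm"`: a list with fields `N`,
#'   `params`, `P` (the `(N+1) x (N+1)` matrix), `v` and `w`.
#' @examples
#' tm <- transition_matrix(ratchet_params(50, 0.02, 0.05))
#' tm$P[1, 1:3]   # absorbing row: 1 0 0
#' @export
transition_matrix <- function(params) {
  params <- .check_params(params)
  N <- params$N
  succ <- deterministic_map((0:N) / N, params$mu, params$sigma)
  P <- matrix(0, N + 1L, N + 1L)
  for (n in 0:N) P[n + 1L, ] <- stats::dbinom(0:N, N, succ[n + 1L])
  if (any(!is.finite(P)))
    stop("non-finite binomial transition probabilities encountered",
         call. = FALSE)
  P[1L, ] <- c(1, rep(0, N))  # absorbing boundary, exact
  dev <- abs(rowSums(P) - 1)
  bad <- which(dev > 1e-12)
  if (length(bad)) {
    message(sprintf("renormalizing %d transition row(s); max deviation %.3g",
                    length(bad), max(dev)))
    P[bad, ] <- P[bad, , drop = FALSE] / rowSums(P[bad, , drop = FALSE])
  }
  structure(
    list(N = N, params = params,
         P = P,
         v = P[2:(N + 1L), 1L],
         w = P[2:(N + 1L), 2:(N + 1L), drop = FALSE]),
    class = "ratchet_tm"
  )
}

#' @export
print.ratchet_tm <- function(x, ...) {
  cat(sprintf("<ratchet_tm> %d x %d one-generation kernel (N = %d, mu = %g, sigma = %g)\n",
              x$N + 1L, x$N + 1L, x$N, x$params$mu, x$params$sigma))
  invisible(x)
}

.check_tm <- function(tm) {
  if (!inherits(tm, "ratchet_tm"))
    stop("expected a `ratchet_tm` object from transition_matrix()",
         call. = FALSE)
  tm
}

#' Propagate a distribution over allele counts through the chain
#'
#' Pushes a probability vector over the states `0, ..., N` forward by `t`
#' generations under the one-generation kernel.  Total mass is conserved and
#' the mass on the absorbing state 0 is non-decreasing in `t`; after a
#' burn-in the surviving mass `1 - p0(t)` shrinks geometrically by the
#' quasi-stationary eigenvalue `lambda1` per generation
#' (see [quasi_stationary()]).
#'
#' @param tm A [transition_matrix()] object.
#' @param dist Non-negative vector of length `N + 1` summing to 1.
#' @param t Number of generations (non-negative integer).
#' @return The propagated probability vector of length `N + 1`.
#' @export
propagate <- function(tm, dist, t) {
  tm <- .check_tm(tm)
  if (length(dist) != tm$N + 1L || any(dist < 0) ||
      abs(sum(dist) - 1) > 1e-8)
    stop("`dist` must be a probability vector over the N + 1 states",
         call. = FALSE)
  if (length(t) != 1L || !is.finite(t) || t != round(t) || t < 0)
    stop("`t` must be a non-negative integer number of generations",
         call. = FALSE)
  dist <- as.numeric(dist)
  for (i in seq_len(t)) dist <- as.vector(dist %*% tm$P)
  dist
}

#' Quasi-stationary distribution of the transient block
#'
#' Conditioned on the fittest class not yet being lost, the distribution of
#' the chain over the transient states `1, ..., N` converges to the
#' (left) Perron vector `q` of the transient block `w`, with leading
#' eigenvalue `lambda1` in (0, 1): `q %*% w = lambda1 * q`.  `lambda1` is the
#' per-generation survival factor and satisfies the flux identity
#' `lambda1 = 1 - sum(v * q)`.
#'
#' Computed by power iteration with renormalization, starting from the
#' uniform distribution over transient states; `w` is strictly positive for
#' interior `mu`, `sigma`, so Perron-Frobenius guarantees convergence.
#'
#' @param tm A [transition_matrix()] object.
#' @param tol Convergence tolerance on the successive-iterate max-norm.
#' @param max_iter Iteration cap; exceeding it is an error that reports the
#'   last residual.
#' @return An object of class `"ratchet_qsd"`: list with `q` (length-`N`
#'   probability vector), `lambda1`, `iterations` and `residual`
#'   (the eigen-equation max-norm residual).
#' @export
quasi_stationary <- function(tm, tol = 1e-12, max_iter = 1e6) {
  tm <- .check_tm(tm)
  q <- rep(1 / tm$N, tm$N)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    qw <- as.vector(q %*% tm$w)
    s <- sum(qw)
    qn <- qw / s
    delta <- max(abs(qn - q))
    q <- qn
    if (delta < tol) break
    if (iter >= max_iter)
      stop(sprintf(paste0("quasi-stationary power iteration did not ",
                          "converge in %d iterations (last step %.3g)"),
                   iter, delta), call. = FALSE)
  }
  lambda1 <- sum(q %*% tm$w)     # equals 1 - v.q up to rounding
  residual <- max(abs(as.vector(q %*% tm$w) - lambda1 * q))
  structure(
    list(q = q, lambda1 = lambda1, iterations = iter, residual = residual),
    class = "ratchet_qsd"
  )
}

#' @export
print.ratchet_qsd <- function(x, ...) {
  cat(sprintf("<ratchet_qsd> lambda1 = %.12g (%d iterations, residual %.3g)\n",
              x$lambda1, x$iterations, x$residual))
  invisible(x)
}

#' Exact mean absorption (click) time of the discrete chain
#'
#' Solves the fundamental-matrix system `(I - w) tau = 1` over the transient
#' states, so `tau[n]` is the expected number of generations until the
#' fittest class is lost (state 0 is hit) when starting from `n` wild-type
#' copies.  This is the exact discrete-chain oracle against which the
#' diffusion-approximation click times are checked.
#'
#' @param tm A [transition_matrix()] object.
#' @param start Start state(s), integer in `0, ..., N`.  Defaults to `N`
#'   (fittest class fixed).
#' @return Mean absorption time(s) in generations; 0 for `start = 0`.
#' @export
mean_absorption_time <- function(tm, start = tm$N) {
  tm <- .check_tm(tm)
  if (any(start != round(start)) || any(start < 0) || any(start > tm$N))
    stop("`start` must be integer state(s) in 0..N", call. = FALSE)
  tau <- tryCatch(
    solve(diag(tm$N) - tm$w, rep(1, tm$N)),
    error = function(e) stop("transient system (I - w) is numerically singular: ",
                             conditionMessage(e), call. = FALSE))
  ifelse(start == 0, 0, tau[pmax(start, 1L)])
}

#' Monte-Carlo samples of the single click time
#'
#' Simulates the ratchet chain by direct binomial sampling: from count `n`
#' the next count is `rbinom(1, N, m(n/N))` with `m` the deterministic
#' mutation-selection map.  Each replicate runs until state 0 (the click:
#' loss of the fittest class) or until `max_gen` generations, in which case
#' it is reported as censored, never dropped.  Identical seeds give identical
#' samples.
#'
#' @param params A [ratchet_params()] object.
#' @param start Start state in `0, ..., N`, or `NULL` for the default:
#'   `round(N * x2)` when the landscape has two interior fixed points
#'   (clicking regime), else `N`.
#' @param reps Number of replicates (at least 1).
#' @param seed Integer seed; recorded in the output.
#' @param max_gen Censoring horizon in generations.
#' @return An object of class `"ratchet_click_sample"`: list with `times`
#'   (censored entries `NA`), `mean`, `se` (standard error over uncensored
#'   replicates), `censored` count, `status` (`"ok"`, or
#'   `"mostly-censored"` when more than half the replicates hit `max_gen`),
#'   plus the `start`, `reps`, `seed` and `max_gen` used.
#' @export
sample_click_times <- function(params, start = NULL, reps, seed,
                               max_gen = 1e7) {
  params <- .check_params(params)
  if (length(reps) != 1L || reps < 1 || reps != round(reps))
    stop("`reps` must be a positive integer", call. = FALSE)
  if (length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  N <- params$N
  if (is.null(start)) start <- .default_start_state(params)
  if (start != round(start) || start < 0 || start > N)
    stop("`start` must be an integer state in 0..N", call. = FALSE)
  set.seed(as.integer(seed))
  state <- rep.int(as.integer(start), reps)
  times <- rep(NA_real_, reps)
  times[state == 0L] <- 0
  alive <- state > 0L
  gen <- 0
  while (any(alive) && gen < max_gen) {
    gen <- gen + 1
    idx <- which(alive)
    succ <- deterministic_map(state[idx] / N, params$mu, params$sigma)
    state[idx] <- stats::rbinom(length(idx), N, succ)
    hit <- idx[state[idx] == 0L]
    if (length(hit)) {
      times[hit] <- gen
      alive[hit] <- FALSE
    }
  }
  censored <- sum(alive)
  status <- if (censored > reps / 2) "mostly-censored" else "ok"
  if (status != "ok")
    warning(sprintf("%d of %d replicates censored at max_gen = %g",
                    censored, reps, max_gen), call. = FALSE)
  obs <- times[!is.na(times)]
  structure(
    list(times = times,
         mean = if (length(obs)) mean(obs) else NA_real_,
         se = if (length(obs) > 1) stats::sd(obs) / sqrt(length(obs)) else NA_real_,
         censored = censored, status = status,
         start = as.integer(start), reps = as.integer(reps),
         seed = as.integer(seed), max_gen = max_gen),
    class = "ratchet_click_sample"
  )
}

#' @export
print.ratchet_click_sample <- function(x, ...) {
  cat(sprintf(paste0("<ratchet_click_sample> %d replicates from state %d: ",
                     "mean %.6g (se %.3g), %d censored [seed %d]\n"),
              x$reps, x$start, x$mean, x$se, x$censored, x$seed))
  invisible(x)
}

# Default Monte-Carlo / CLI start state: the upper interior fixed point when
# the landscape has a well-defined two-peak (clicking) structure, else the
# fixed-fittest-class boundary state N.
.default_start_state <- function(params) {
  rep <- classify_regime(params)
  x2 <- Re(rep$x2)
  if (rep$regime == "I iv") as.integer(round(params$N * x2)) else params$N
}
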