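# Built-in parameter scenarios: the canonical parameter sets used
# throughout the package's examples, tests and command-line reports.

#' Built-in parameter scenarios
#'
#' A curated list of parameter sets covering the qualitatively distinct
#' shapes of the adaptive landscape: the finite-barrier clicking regime
#' (`I iv`, two interior fixed points), the low-mutation infinite-barrier
#' regime (`I iii`), the narrow near-double-root band around the
#' discriminant-zero curve, and a larger-population sweep of
#' high-versus-low mutation rates.  Every scenario passes strict
#' validation (`sigma > mu`).
#'
#' `expected_regime` records the regime label the scenario is intended to
#' illustrate.  For the three `near_double_root` scenarios the intended
#' label is `"I i"`, but they sit within about `1e-4` of the double-root
#' and root-at-one threshold curves, where the discriminant classification
#' is extremely sensitive; these carry `verified = FALSE` and the
#' classifier's own answer should be trusted over the label.  For the
#' larger-population sweep no selection coefficient is canonical, so each
#' `sigma` is placed mid-band inside the intended regime using
#' [critical_thresholds()].
#'
#' @return An object of class `"ratchet_scenarios"`: a named list of
#'   scenarios, each a list with `name`, `params`, `source` (free-text
#'   provenance note), `expected_regime` and `verified`.
#' @examples
#' names(scenario_fixtures())
#' @export
scenario_fixtures <- function() {
  mk <- function(name, N, mu, sigma, expected, source, verified = TRUE) {
    list(name = name,
         params = ratchet_params(N, mu, sigma, strict = TRUE),
         source = source, expected_regime = expected, verified = verified)
  }
  mid_sigma <- function(N, mu, low) {
    th <- critical_thresholds(N, mu)
    if (low) (th$sigma_unity + 1) / 2
    else (th$sigma_double + th$sigma_unity) / 2
  }
  N100_mus <- c(210, 500, 1000) / 39600
  sc <- list(
    mk("clicking_moderate", 50, 0.02, 0.05, "I iv",
       "canonical finite-barrier clicking scenario (two interior fixed points)"),
    mk("clicking_strong_selection", 50, 0.02, 0.1, "I iv",
       "clicking regime with stronger selection"),
    mk("clicking_extreme_rates", 50, 0.4, 0.9, "I iv",
       "clicking regime at high mutation and near-lethal selection"),
    mk("low_mu_infinite_barrier", 50, 0.000005, 0.00005, "I iii",
       "canonical low-mutation scenario: infinite barrier at x = 1"),
    mk("low_mu_strong_selection", 50, 0.000005, 0.01010, "I iii",
       "low mutation with selection-dominated dynamics"),
    mk("low_mu_matched_rates", 50, 0.01, 0.01012, "I iii",
       "mutation and selection nearly balanced, 2 N mu at unity"),
    mk("near_double_root_a", 50, 0.0101015, 0.010102, "I i",
       "just off the double-root curve; discriminant marginally negative",
       verified = FALSE),
    mk("near_double_root_b", 50, 0.0101015, 0.0102, "I i",
       "narrow band near the root-at-one curve", verified = FALSE),
    mk("near_double_root_c", 50, 0.0101015, 0.01015, "I i",
       "narrow band near the root-at-one curve", verified = FALSE)
  )
  for (i in seq_along(N100_mus)) {
    mu <- N100_mus[i]
    sc <- c(sc, list(
      mk(sprintf("N100_high_barrier_mu%d", i), 100, mu,
         mid_sigma(100, mu, low = FALSE), "I iv",
         "larger population, sigma mid-band between the double-root and root-at-one curves")))
  }
  for (i in 1:2) {
    mu <- N100_mus[i]
    sc <- c(sc, list(
      mk(sprintf("N100_low_regime_mu%d", i), 100, mu,
         mid_sigma(100, mu, low = TRUE), "I iii",
         "larger population, sigma above the root-at-one curve (x = 1 adaptive)")))
  }
  names(sc) <- vapply(sc, `[[`, "", "name")
  structure(sc, class = "ratchet_scenarios")
}

#' @export
print.ratchet_scenarios <- function(x, ...) {
  cat(sprintf("<ratchet_scenarios> %d scenarios\n", length(x)))
  for (s in x) {
    cat(sprintf("  %-28s N = %-4d mu = %-12g sigma = %-12g expect %s%s\n",
                s$name, s$params$N, s$params$mu, s$params$sigma,
                s$expected_regime,
                if (s$verified) "" else " (unverified)"))
  }
  invisible(x)
}
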