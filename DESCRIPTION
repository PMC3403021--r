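Package: ratchetclick
Title: Adaptive Landscape and Click Times for Muller's Ratchet
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the one-locus, two-allele Wright-Fisher model of
    Muller's ratchet in a finite asexual population subject to
    irreversible deleterious mutation, viability selection and random
    drift.  Implements the discrete absorbing Markov chain (transition
    matrix, quasi-stationary distribution, exact mean absorption times,
    Monte-Carlo click-time sampling), the diffusion approximation with
    its closed-form adaptive landscape and boundary classification, the
    complete taxonomy of fixed-point regimes over the mutation-selection
    parameter plane, and the mean single click time (first passage to
    loss of the fittest class) by numerical quadrature, saddle-point and
    closed-form approximations, with all layers cross-validating each
    other.  A small command-line front end writes reproducible TSV and
    JSON reports.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
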