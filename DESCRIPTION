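Package: ratchetr
Title: Muller's Ratchet with Overlapping Generations: Simulators, Exact
    Click Times and WKB Asymptotics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying Muller's ratchet, the irreversible loss of
    the least-loaded mutation class in a finite asexual population. Provides
    exact stochastic simulators of the multi-class Moran model with
    overlapping generations, Haigh's Wright-Fisher model and the mesoscopic
    diffusion (SDE) limit; the reduction to an effective two-class Moran
    birth-death chain with the mutation-selection parameter mapping; the
    exact mean first-passage (click) time of the reduced chain; a
    dominant-eigenpair solver for the quasi-stationary distribution (QSD) of
    the fittest class; and WKB (eikonal) approximations of the ratchet rate
    and of the QSD in the rare-clicking regime, including a large-N*s
    simplification and its scaling decomposition with an analytic,
    lambda-dependent Haigh factor.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
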