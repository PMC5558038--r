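Package: chronoddm
Title: Bounded Evidence Accumulation Models for Subjective Decision Times
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether subjective decision times reported by
    mental chronometry mark the termination of a bounded evidence-accumulation
    (drift-diffusion) process. Provides simulators for random-dot motion
    discrimination experiments (controlled-duration and free-response designs),
    closed-form fitting of mean subjective decision times with a flat-bound
    drift-diffusion model and prediction of choice accuracy from those fits,
    numerical first-passage-time densities under collapsing bounds with gamma
    non-decision latencies, maximum-likelihood and Metropolis posterior
    inference, Jensen-Shannon goodness of fit with bootstrap and permutation
    nulls, surrogate sensitivity analyses of the choice predictions, and a
    frequency-domain motion-energy reverse correlation of the dot movies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
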