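Package: petrand
Title: Random Coincidence Identification and Estimation for PET, Including
    Triple Coincidences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Event-stream tools for positron emission tomography (PET)
    coincidence processing. Generates ground-truth-labelled synthetic
    list-mode singles streams under a homogeneous-Poisson decay model with
    per-decay detection efficiencies, Gaussian coincidence-timing jitter,
    optional non-paralyzable dead time and prompt-gamma emission for
    beta+-gamma emitters. Identifies prompt double, triple and higher-order
    multiple coincidences under four veto schemes (no veto, between, inner,
    outer), and estimates random double and random triple rates with
    extended delayed-window techniques: ratio combinations of delayed
    window schemes for doubles, one-delay/two-delay subtraction for
    two-decay triples of beta+ emitters, scale-scheme corrections for
    three-decay triples, and the combined estimator for two-decay triples
    of beta+-gamma emitters. Includes analytic activity-dependence rate
    models, weighted curve fitting, and an experiment driver that sweeps
    activities with repetitions and reports estimator deviations against
    decay-ID ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
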