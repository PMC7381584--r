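Package: pollinet
Title: Null-Model Preference and Visitation-Rate Analysis for Plant-Pollinator Communities
Version: 0.1.0
Authors@R:
    person("Pollinet", "Developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for community-wide analysis of honey-bee versus
    wild-pollinator use of introduced and native plants: floral-abundance
    estimation from quadrat stem counts, negative-binomial visitation-rate
    models with exposure offsets and crossed random effects, a marginal-total
    constrained null-model preference index built on an own implementation of
    Patefield-style contingency-table sampling (including continuous-entry and
    one-dimensional degenerate cases), per-netting-period bee diversity models,
    apiary pollen summaries, and a synthetic-data generator with known ground
    truth so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    lme4,
    mvtnorm,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
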