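Package: kdbym
Title: Bayesian Spatiotemporal Disease Mapping for Kawasaki Disease Incidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for small-area spatiotemporal analysis of rare paediatric
    disease incidence, built around the Besag-York-Mollie (BYM) hierarchical
    Poisson model with linear, random-walk and seasonal temporal effects.
    Includes population-driven aggregation of small spatial units into
    analysis regions, covariate preparation (standardization, pollutant
    combination, nearest-station and grid-to-region assignment), a
    Metropolis-within-Gibbs sampler with WAIC computation, WAIC-based
    univariable screening and backward elimination of covariates,
    observed-versus-modelled rate evaluation, and a synthetic-data generator
    emulating monthly region-level case panels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
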