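Package: yieldparts
Title: Yield Component Decomposition and Comparative Analysis for Crop
    Domestication Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for dissecting how domestication changed the seed yield
    of cereal and pulse crops relative to their wild progenitors. Decomposes
    per-plant yield into growth and allocation components (sown seed mass,
    average relative growth rate, growth duration, reproductive allocation,
    chaff proportion) and into seed-packaging components (seed mass, seeds
    per infructescence, infructescences per plant); apportions the variance
    in yield among traits with a first-order delta-method decomposition that
    retains trait covariances; estimates size-corrected relative growth
    rates from four-parameter logistic fits to harvest series; and tests
    crop-versus-progenitor contrasts on species means with phylogenetic
    generalized least squares under a maximum-likelihood Pagel's lambda
    correlation structure. Includes a synthetic-data generator that emulates
    the randomized-block greenhouse design of a two-experiment landrace
    versus wild-progenitor comparison, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
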