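Package: stmixmap
Title: Multivariate Space-Time Mixture Models for Small-Area Disease Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Bayesian disease mapping with spatio-temporal mixture models for
    one to three diseases observed as county-by-year incidence counts. The
    log relative risk is a convex mixture of spatial, temporal and
    spatio-temporal linear-predictor components with county-level mixture
    weights built from a CAR-correlated and an uncorrelated logit field.
    Five model variants are provided (F2PRED, Alt1, Alt2, Alt3a, Alt3b),
    differing in whether the random-walk temporal effect is shared across
    diseases, disease-specific, scaled, or split into its own mixture
    component. Includes threshold-censored count imputation via truncated
    Poisson sampling, expected counts and standardized incidence ratios,
    an adaptive Metropolis-within-Gibbs sampler, WAIC/MSPE model
    assessment with per-disease and year-window decomposition, and a
    synthetic lattice data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'assessment.R'
    'cli.R'
    'data-io.R'
    'inference.R'
    'model-family.R'
    'preprocess.R'
    'stmixmap-package.R'
    'synthetic.R'
    'utils.R'
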