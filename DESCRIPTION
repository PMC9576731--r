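Package: nestbym
Title: Nested Two-Level Bayesian Spatio-Temporal Models for Areal Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits hierarchical Bayesian spatio-temporal Poisson models for
    areal count panels observed on a fine spatial level (e.g. provinces)
    nested inside a coarse level (e.g. natural geographic regions). Both
    levels carry structured (intrinsic CAR) and unstructured spatial
    effects, time carries first-order random-walk and exchangeable effects,
    and space-time interactions at each level take one of the four
    Knorr-Held types built from Kronecker products of the marginal
    structure matrices. Includes a Metropolis-within-Gibbs sampler with
    likelihood-preconditioned block proposals, a dense-grid posterior
    oracle for tiny sub-models, DIC/WAIC computation with a two-stage
    interaction-type selection procedure, a synthetic nested-lattice data
    generator, and relative-risk decomposition reports with risk-band
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
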