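Package: remvar
Title: Reference Effect Measures for Cluster Variation in Multilevel Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies, compares and visualizes unexplained cluster variation
    (general contextual effects) and variation from sets of fixed effects in
    non-normal multilevel models using reference effect measures (REM) on the
    effect (odds-ratio) scale. Includes a random-intercept generalized linear
    mixed model fitter based on adaptive Gauss-Hermite quadrature, comparison
    measures (median odds ratio, per-SD odds ratio, individual outcome
    measures, latent-scale intraclass correlation), delta-method and cluster
    bootstrap confidence intervals, a two-level synthetic data generator, and
    forest-plot style displays of REM distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
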