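Package: lipaseQSAR
Title: QSAR Models of Alkaline Lipase Substrate Specificity and
    Mixed-Oil Activity Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantitative structure-activity relationship (QSAR) modeling
    of the ester-hydrolysis activity of three alkaline lipases (L-A1,
    L-A2, L-A3). Provides descriptor-table data structures with bundled
    study tables, linear-plus-spline QSAR models with ordinary
    least-squares fitting and the full validation-statistics suite
    (R-squared, adjusted R-squared, F, Friedman lack-of-fit,
    leave-one-out cross-validated q2), a genetic function approximation
    (GFA) engine for descriptor-subset search under lack-of-fit fitness,
    an optional genetic partial-least-squares refinement, a registry of
    the three published lipase equations, a mole-fraction-weighted
    mixture predictor for the hydrolysis activity of natural oils, and a
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
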