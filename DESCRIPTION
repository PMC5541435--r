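Package: hillsurf
Title: Hill Response Surfaces as Null-Interaction Models for Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates and compares null-interaction reference models for
    the combined effect of agent mixtures with sigmoid (Hill) dose-response
    curves. Implements the n-component Hill response surface obtained as the
    closed-form solution of a logistic partial differential equation with
    sham-compliance and single-agent boundary conditions, together with the
    standard references it subsumes or contradicts: Bliss independence
    (Colby's formula), Loewe concentration addition, generalized
    concentration addition, the Chou-Talalay exclusive and non-exclusive
    median-effect models, and Greco's interaction model. Provides Hill-curve
    fitting by multi-start nonlinear least squares, mixture prediction with
    RMSE scoring, isobole and ternary iso-surface extraction,
    difference-surface grids, numeric verification oracles (PDE residual,
    sham-compliance and boundary-condition deviations), seeded synthetic
    data generators, CSV/JSON input and output, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
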