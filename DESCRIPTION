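Package: inqolval
Title: Utility Valuation of the 8-Dimension INQoL by Hybrid cTTO-DCE Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to estimate a preference-based utility tariff for an
    8-dimension subset of the Individualized Neuromuscular Quality of Life
    questionnaire (INQoL), as used in economic evaluation of treatments for
    non-dystrophic myotonia. Builds the strength-2 orthogonal valuation
    designs for composite time trade-off (cTTO) interviews and a discrete
    choice experiment (DCE) with Street-shifted pairs, simulates respondent
    data with censored heteroscedastic TTO values and logit choices, fits
    main-effects, linear and cross-attribute level effects (CALE) value
    models separately or as TTO+DCE hybrids by constrained maximum
    likelihood, selects models by leave-one-state-out cross-validation, and
    converts the chosen fit into a dimension-by-level disutility tariff
    (with midpoint interpolation of unobserved levels and monotonicity
    repair) for scoring questionnaire responses to utilities for QALY
    estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
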