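Package: fflscreen
Title: Feed-Forward-Loop Module Inference from qPCR Perturbation Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of small-scale genetic-perturbation expression screens
    measured by qRT-PCR array cards. Implements comparative cycle-threshold
    (delta-delta-CT) pre-processing with reference-gene selection, a fitted
    measurement-error model of delta-delta-CT biological variance
    (sigma^2 = alpha + beta * |ddCT|^gamma, fitted on binned replicate
    variances by weighted least squares), a two-stage significance-selection
    procedure (variance-percentile filter, model-based z-test of H0: ddCT = 0,
    Bonferroni family-wise error control), and reconstruction of signed,
    phase-annotated multi-output feed-forward-loop (FFL) regulatory modules
    from pairs of perturbed candidate modulators. A synthetic-screen generator
    with planted ground-truth networks makes the whole pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
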