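Package: ivtbo
Title: Bayesian Optimization of mRNA In Vitro Transcription Reactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Closed-loop Bayesian optimization of mRNA in vitro transcription
    (IVT) reaction conditions. Defines the mixed categorical/integer/real
    12-parameter IVT search space, seeds the loop with Latin hypercube designs,
    fits a Gaussian-process surrogate with an anisotropic (ARD) Matern 5/2
    kernel by marginal-likelihood point estimation, proposes batches of 3-5
    reaction conditions by expected improvement with a diversity rule, explains
    surrogate predictions with Shapley sampling values, and compares surrogate
    families by leave-one-out cross-validation. Ships a synthetic IVT
    yield-and-kinetics simulator calibrated to published optimized reaction
    yields so the whole loop can be exercised and validated in silico.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    ranger,
    testthat (>= 3.0.0),
    xgboost
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
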