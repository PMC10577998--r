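Package: ecotmle
Title: Targeted Learning for Ordinal Exposures in Country-Level Burden Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Doubly-robust targeted maximum likelihood estimation (TMLE) of
    counterfactual mean log-burden at each level of an ordinal exposure on
    ecological (country-level) panels, with a cross-validated stacking
    ensemble (super learner) for the outcome regression and the multinomial
    exposure mechanism, stabilized and percentile-trimmed inverse-probability
    weights, influence-curve inference, saturated marginal-structural-model
    contrasts against a reference level, positivity diagnostics, a
    sensitivity grid over trimming levels and outlier removal, and a
    synthetic country-panel generator with analytically known causal truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    MASS,
    nnet,
    pracma,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
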