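Package: methaneval
Title: Evaluation of Empirical Enteric Methane Prediction Models for Dairy Cattle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking empirical enteric methane (CH4) prediction
    equations for dairy cattle against treatment-mean databases. Ships a
    registry of 40 published prediction equations; computes mean square
    prediction error and its mean-bias / slope-bias / random-error
    decomposition, Lin's concordance correlation coefficient with its
    location- and scale-shift components, the coefficient of determination,
    and the RMSPE-to-observed-SD ratio (RSR) used for model ranking; fits
    St-Pierre residual regressions on centered predictions to separate mean
    from linear bias; and generates synthetic treatment-mean databases with a
    Gaussian copula, truncated-normal marginals, realistic missingness and a
    dry-matter-intake-driven methane mechanism, so the full pipeline is
    testable without access to an assembled literature database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
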