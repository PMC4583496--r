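Package: missbench
Title: Benchmarking Missing-Data Strategies for Clinical Risk Prediction Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies how missing-data handling strategies (complete-case
    deletion, unconditional mean/mode imputation, conditional mean imputation,
    stochastic regression imputation, and multiple imputation by chained
    equations) affect the external-validation performance of logistic risk
    prediction models, with application to undiagnosed diabetes screening.
    Provides a synthetic cohort generator emulating a South African
    community-based diabetes study (marginal distributions, missingness rates,
    and a known outcome-generating logistic model), MCAR/MAR/MNAR amputation,
    native implementations of the five strategies including fully conditional
    specification multiple imputation with Rubin's-rules pooling, a declarative
    logistic risk-score engine with intercept recalibration, and discrimination
    and calibration metrics (C-statistic with DeLong confidence intervals,
    Brier score, Yates slope, expected/observed ratio with Poisson intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    nnet,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
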