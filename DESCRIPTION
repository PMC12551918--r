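Package: ridgepen
Title: Ridge Penalty Selection and Multicollinearity Diagnostics for Linear Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for ridge regression in canonical form with a catalog of
    fourteen data-driven choices of the ridge constant, including two
    condition-number-adaptive penalties whose shrinkage strength grows with
    the severity of multicollinearity.  Provides correlation-based
    collinearity diagnostics (variance inflation factors, condition number,
    Farrar-Glauber statistic), a Monte Carlo framework comparing estimators
    by estimated mean squared error under equicorrelated Gaussian designs,
    and real-data evaluation metrics (plug-in mean squared error, absolute
    and relative shrinkage, prediction-interval coverage).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
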