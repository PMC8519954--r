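Package: stabkin
Title: Arrhenius Kinetic Modelling of Accelerated Stability Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predicts long-term stability of therapeutic proteins at the
    intended storage temperature from short-term accelerated stability data.
    Fits a first-order degradation model jointly across storage temperatures
    through the Arrhenius rate law, constructs Monte-Carlo 95% probability
    confidence and prediction intervals for the extrapolated trajectory,
    assesses model robustness by temperature sub-sampling, compares against
    the ICH-style linear-regression baseline, and verifies predictions with
    coverage and interval-width statistics. Includes a synthetic
    stability-study generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
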