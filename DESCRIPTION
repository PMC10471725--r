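Package: mlecont
Title: Continuation of Maximum Likelihood Estimators in Calibration-Data Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Numerical continuation of maximum likelihood estimators (MLEs) for
    dynamical models of biological systems. Given a fitted ODE model, the package
    computes the Jacobian of the best-fit parameter vector with respect to the
    calibration data via the implicit function theorem, predicts the MLE for
    perturbed data sets without re-optimisation (predictor step), refines
    predictions with a bounded least-squares corrector, and turns the
    data-to-parameter Jacobian into experimental-design quantities:
    per-data-point MLE sensitivity, most-informative measurement selection,
    candidate time-point ranking, and robustness comparison of competing local
    minima. Ships a target-cell-limited viral dynamics model, a synthetic
    phenotype-switching tumour growth model, a closed-form linear test model,
    and seeded generators for all simulated calibration data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
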