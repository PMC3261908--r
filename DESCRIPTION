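Package: promoterlogic
Title: Promoter Logic Functions and Feedback Response Prediction for
    LuxI/LuxR Quorum Sensing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing the two-input promoter logic function
    (PLF) of the LuxR-regulated pR promoter and for predicting the
    density-dependent responses of quorum-sensing feedback circuits built on
    it. Includes a synthetic-data generator for replicated inducer-grid
    fluorescence measurements with multiplicative log-normal noise,
    affine fluorescence calibration (lines of equivalence), nonlinear
    least-squares PLF parameter estimation with a fixed-cooperativity sweep
    and Monte-Carlo goodness of fit, model-independent steady-state
    prediction by power-law interpolation and line-of-equivalence
    intersection, density-dependent response computation with
    monostable/bistable/hysteretic classification and fold-bifurcation
    mapping, and phase-plane analysis of a dual positive/negative-feedback
    oscillator (nullclines, linear stability, Hopf boundary, limit cycles).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
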