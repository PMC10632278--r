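Package: hhimmunity
Title: Herd Immunity Levels in Household-Structured SEIR Epidemic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for computing and comparing herd immunity levels in
    SIR/SEIR epidemic models for populations partitioned into households,
    with uniform global mixing and an elevated within-household contact
    rate. Implements exact single-household final-outcome algebra
    (triangular recursions of Gontcharoff type), the population final-size
    fixed point, household reproduction numbers (the household threshold
    parameter and the rank-generation basic reproduction number), growth
    rate calibration via a household Lotka-Euler equation, the deterministic
    ODE limit of the household SEIR process, a stochastic household
    simulator, and solvers for the vaccine-induced herd immunity level and
    for disease-induced herd immunity levels (exact along the ODE trajectory
    and via the reduced-global-rate final-size approximation), together with
    closed forms and ordering classifiers for the highly and weakly locally
    infectious limits.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
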