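Package: dlpoppk
Title: Population Pharmacokinetics of Once-Daily Dolutegravir/Lamivudine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population pharmacokinetic analysis of the once-daily
    dolutegravir 50 mg / lamivudine 300 mg fixed-dose combination at steady
    state. Implements the final one-compartment (dolutegravir) and
    two-compartment (lamivudine) first-order absorption models with covariate
    effects on clearance and volume, log-normal inter-individual variability
    including variability on the proportional residual-error magnitude,
    closed-form steady-state concentration prediction, a virtual-population
    generator emulating the study design (intensive and sparse sampling,
    below-quantification flagging), Laplace-approximation nonlinear
    mixed-effects estimation with forward/backward covariate selection and
    nonparametric bootstrap, noncompartmental steady-state exposure metrics
    (AUC0-tau, Cmax, Ctau) with covariate forest-plot trial simulation, and
    model diagnostics (prediction-corrected visual predictive checks,
    normalised prediction distribution errors, goodness-of-fit summaries).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    pracma,
    stats,
    utils,
    tools,
    yaml
Suggests:
    deSolve,
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
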