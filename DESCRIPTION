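Package: hairpk
Title: Joint Plasma-Hair Population Pharmacokinetics of Boosted Atazanavir
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Population pharmacokinetic modelling of antiretroviral drug
    concentrations measured in hair, treating the hair concentration as a
    fraction of the steady-state plasma trough of a fixed one-compartment
    first-order-absorption plasma model. Provides the structural depot-
    central-hair compartment model with closed-form and ODE solvers,
    nonlinear mixed-effects estimation by Laplace approximation of the
    marginal likelihood (with an adaptive Gauss-Hermite quadrature oracle),
    stepwise covariate selection on the hair fraction with delta-OFV
    criteria, nonparametric subject-level bootstrap confidence intervals,
    goodness-of-fit diagnostics (IWRES, CWRES), and a synthetic-cohort
    generator emulating an adolescent atazanavir/ritonavir adherence study
    with assay-range censoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    ggplot2,
    jsonlite,
    MASS,
    patchwork,
    pracma,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
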