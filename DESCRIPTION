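Package: vancoppk
Title: Population Pharmacokinetics of Vancomycin in Postoperative
    Neurosurgical Patients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population pharmacokinetic (PPK) analysis of
    intravenous vancomycin in adult postoperative neurosurgical patients.
    Implements closed-form one-compartment infusion kinetics, Cockcroft-Gault
    and CKD-EPI renal function equations, a covariate model for clearance,
    FOCE-type nonlinear mixed-effects estimation with a single log-normal
    random effect on clearance and a combined residual error model, stepwise
    covariate selection by objective-function-value criteria, nonparametric
    subject-level bootstrap, visual predictive checks, Monte Carlo dose
    finding targeting steady-state AUC24, and a synthetic-cohort generator
    emulating the trough-dominated therapeutic drug monitoring design of a
    neurosurgical intensive-care population.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
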