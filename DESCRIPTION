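Package: tigeppk
Title: Population Pharmacokinetics and Dose Optimization of Tigecycline in
    Critically Ill Patients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population pharmacokinetic (PPK) analysis of
    tigecycline in critically ill patients: an analytic two-compartment
    zero-order-infusion structural model, covariate submodels (linear,
    exponential, power and categorical forms with Cockcroft-Gault creatinine
    clearance), FOCE-type nonlinear mixed-effects estimation with
    forward-inclusion/backward-elimination covariate selection,
    goodness-of-fit, bootstrap and visual-predictive-check diagnostics, and
    Monte Carlo probability-of-target-attainment (PTA) simulation over
    AUC/MIC targets for dosing-regimen optimization. A synthetic cohort
    generator emulating an intensive-sampling critical-care study design
    allows the whole pipeline to run and be tested without patient-level
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
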