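Package: acetapop
Title: Population Pharmacodynamics of Acetazolamide in Ventilated COPD
    Patients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Population pharmacokinetic/pharmacodynamic modelling of the
    serum bicarbonate response to acetazolamide in invasively ventilated
    patients with chronic obstructive pulmonary disease.  Implements an
    indirect-response (turnover) model in which the drug stimulates
    bicarbonate elimination through an Emax function of the body drug
    amount, a covariate submodel (SAPS II, serum chloride,
    glucocorticoids on baseline; furosemide on the elimination rate),
    nonlinear mixed-effects estimation by Laplace or adaptive
    Gauss-Hermite quadrature, simulation-based model diagnostics
    (normalized prediction distribution errors with decorrelation),
    a synthetic study generator emulating the original design, and a
    dosing-regimen scenario engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    deSolve,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
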