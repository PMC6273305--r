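Package: pkpdlink
Title: Sequential PK-PD Modelling of Antipyretic Response with an
    Effect-Compartment Link
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sequential pharmacokinetic-pharmacodynamic (PK-PD)
    analysis of antipyretic drug response: non-compartmental analysis (Cmax,
    Tmax, lambda_z, AUC, MRT, CL/F), closed-form one- and two-compartment
    extravascular models with optional absorption lag time fitted by weighted
    least squares and ranked by AIC, an effect-compartment (ke0) link with
    linear, hyperbolic Emax and Sigmoid Emax pharmacodynamic models fitted
    against control-corrected rectal-temperature change, hysteresis-loop
    diagnostics, and a virtual-trial simulator for parameter-recovery studies.
    Ships the mean baicalin/geniposide concentration and temperature-change
    profiles of a single-dose antipyresis study in pyrexia-model rats as a
    built-in fixture and a one-call pipeline that reproduces the full analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    deSolve,
    lhs,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
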