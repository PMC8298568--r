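Package: fontanlpn
Title: Closed-Loop Lumped-Parameter Modelling of Fontan Circulation with
    Tissue-Engineered Vascular Grafts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for studying how stenosis of a
    tissue-engineered Fontan conduit affects single-ventricle circulation.
    Provides a closed-loop lumped-parameter (0D) model of Fontan physiology
    with a time-varying-elastance single ventricle, a reduced-order graft
    segment with an empirical stenosis pressure-loss element and
    Laplace-law compliance, metabolic-equivalent (MET) exercise scaling of
    vascular resistance and heart rate, blood-volume compensation of
    stenosis, Fick-principle oxygenation metrics, systemic and venous
    pressure metrics, and local hemodynamic metrics (time-averaged wall
    shear stress, oscillatory shear index, Green-strain invariant,
    residence time).  Includes a synthetic patient-cohort generator and a
    study driver for stenosis-by-exercise sweeps across graft comparison
    arms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
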