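Package: narange
Title: Input Dynamic Range of Negatively Auto-Regulated Gene Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the input dynamic range of gene input
    functions and to study how negative auto-regulation (NAR) of a
    transcription factor widens it, modelled on the L-arabinose
    utilization system of Escherichia coli.  The package simulates
    plate-reader reporter experiments (OD600 and GFP kinetics under
    logistic growth), extracts promoter activities (dGFP/dt per OD) over
    an exponential-phase window, fits Hill input functions with
    bootstrap standard errors, computes the 10--90% input dynamic range
    R (analytically, R = 81^(1/n), and numerically by bisection),
    implements the steady-state NAR model in which the regulator level
    grows as the square root of the inducer signal, scans model
    parameters for the maximal attainable R at a given promoter
    cooperativity, and fits a mass-action model of a dual
    activator/repressor transcription factor to parental and
    constitutive-regulator input functions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
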