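Package: pepvax
Title: Mechanistic Simulation of Short-Peptide Cancer Vaccine Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mechanistic simulation of intradermal short-peptide cancer
    vaccination, from peptide competition for dendritic-cell MHC-I at the
    injection site (mass-action ordinary differential equations with vascular
    clearance), through dendritic-cell migration to the draining lymph node,
    to an agent-based model of cognate T-cell activation in the paracortex.
    Virtual-patient cohorts are pushed through the full pipeline to produce
    responder-count histograms for simulated clinical trials, population
    hyperparameters can be fitted to an observed responder histogram by
    Approximate Bayesian Computation, and intervention-design variants
    (peptide removal, reduced lymphatic transit time) can be compared.
    Includes a synthetic-data generator for peptide panels, ground-truth
    patient populations and observed histograms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
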