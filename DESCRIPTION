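Package: pbpkddi
Title: Physiologically Based Pharmacokinetic Simulation of
    Transporter-Mediated Drug-Drug Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-body physiologically based pharmacokinetic (PBPK)
    simulator for predicting transporter- and enzyme-mediated drug-drug
    interactions (DDIs). Implements validated compound parameter records,
    Rodgers-Rowland tissue-to-plasma partitioning, retrograde derivation of
    intrinsic clearance from oral clearance, a Q_gut-style intestinal
    first-pass model, dynamic CYP3A4 inactivation and induction, a
    mechanistic electrochemical-gradient kidney model for OCT2/MATE-mediated
    renal secretion, an OATP1B1/1B3 hepatic-uptake victim model,
    virtual-population crossover trials with geometric-mean-ratio statistics,
    noncompartmental analysis, sensitivity sweeps, and a synthetic
    concentration-time data generator for calibration and parameter-recovery
    testing. Ships curated parameter records for dasatinib as perpetrator and
    metformin, pravastatin, rosuvastatin and simvastatin as victims.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
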