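Package: dmpkr
Title: Bioanalytical Method Validation and Preclinical DMPK Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical engine for a small-molecule preclinical drug
    metabolism and pharmacokinetics (DMPK) workflow built on LC-MS/MS
    quantitation. Implements weighted (1/x, 1/x^2) calibration regression with
    back-calculation and the ICH M10 batch-acceptance statistics (accuracy,
    precision, recovery, matrix effect, carryover, selectivity, storage
    stability); microsomal half-life fitting and in vitro-in vivo
    extrapolation of hepatic clearance through the well-stirred model with a
    logP-based microsomal-binding correction; equilibrium-dialysis protein
    binding, blood-to-plasma partitioning, kinetic solubility, and PAMPA and
    Caco-2 apparent permeability with sample-withdrawal correction;
    non-compartmental analysis of concentration-time profiles (Cmax, AUC,
    terminal slope, clearance, volume, bioavailability); tissue and unbound
    brain-penetration metrics (Kp, Kp,uu); and seeded synthetic-data
    generators with known ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
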