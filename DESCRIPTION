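Package: xenopkpd
Title: Pharmacokinetic-Pharmacodynamic Simulation of Carboplatin and
    BH3-Mimetic Combination Therapy in Tumor Xenografts
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the growth of ovarian cancer xenografts under
    combination therapy with carboplatin and the Bcl-xL inhibitor ABT-737.
    Couples three-compartment pharmacokinetic models for both drugs to a
    mass-action model of the intracellular Bcl-xL/Bax apoptosis switch and
    to a logistic tumor population with an age-structured, carboplatin-
    arrested compartment solved along characteristics. Provides staged
    least-squares calibration against per-arm tumor-growth-inhibition time
    courses, a synthetic xenograft study generator, and therapy-analysis
    tools: combination-index minimization under a growth-inhibition
    constraint, carboplatin infusion-duration and Bax-sensitivity scans,
    and acquired/intrinsic drug-resistance scenario simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
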