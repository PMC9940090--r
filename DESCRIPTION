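Package: cipaddi
Title: In Silico Torsade de Pointes Risk of Two-Drug Combinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation of drug and drug-pair proarrhythmia (torsade de
    pointes) risk in the CiPA paradigm. Implements the O'Hara-Rudy human
    ventricular endocardial myocyte with CiPA-optimized conductance
    scaling and hERG Markov gating, multi-channel Hill conductance block,
    allotopic (independent-site) and syntopic (shared-site) two-drug
    interaction models, pacing protocols, biomarker extraction (APD90,
    CaD90, qNet, steepest repolarization gradient), qNet-threshold risk
    classification, and drug-combination risk maps over populations of
    bootstrap (IC50, Hill) samples.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
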