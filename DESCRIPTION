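Package: therawin
Title: Therapeutic Window Estimation from Logical Signaling-Network Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the therapeutic window of targeted drugs from
    patient-specific weighted-sum Boolean models of a signaling network.
    Genomic alteration profiles are mapped to ternary node-status clamps that
    rewire a nominal network; drug action is simulated as probabilistic
    dose-dependent inhibition of nodes or individual links; dose-response
    curves over the attractor landscape yield efficacy, potency (IC50),
    toxicity, simulated minimum-effective and maximum-tolerated doses, and
    combination indices. Responses are classified into twelve selective/
    optimal-control categories, screened over single and pairwise node/link
    perturbations (triangle maps), and cohorts are stratified through critical
    genomic determinants and their dominance hierarchy. Includes generators
    for synthetic networks and cohorts with implanted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
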