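Package: phosrelay
Title: Mass-Action Modeling of a Dual-Cluster Bacterial Chemotaxis
    Phosphotransfer Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic mass-action kinetics for the two-cluster
    chemotaxis phosphotransfer network of Rhodobacter sphaeroides: two
    histidine kinases (CheA2, CheA3) feeding five response regulators
    (CheY3, CheY4, CheY6, CheB1, CheB2) through reversible
    phosphotransfer, autodephosphorylation, and the bifunctional CheA3
    kinase-phosphatase acting on CheY6-P. Provides steady-state solvers,
    signal-termination half-time protocols under in-silico genetic
    perturbations (knockouts, phosphatase removal, single-reaction
    ablation), stimulation timelines, one-at-a-time parameter
    sensitivity scans, a synthetic in-vitro phosphotransfer assay
    generator with multiplicative noise, and rate-constant estimation
    from assay time courses by local least squares and differential
    evolution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
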