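Package: arsmet
Title: Kinetic Modeling of Glutathione Effects on Hepatic Arsenic Methylation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Nine-species kinetic ODE model of arsenic methylation by AS3MT in
    liver reaction mixtures, with three distinct glutathione (GSH) effects:
    acceleration of the two reduction steps, Hill-type activation of the
    methyltransferase, and reversible mass-action sequestration of trivalent
    arsenicals as GSH conjugates. Provides stiff integration with conservation
    guarantees, preset in-silico experiments (substrate-inhibition sweeps, time
    courses, GSH dose-response with an interior optimum, ablation variants, and
    methylation-flux dynamics under GSH decay), interval-constraint calibration
    of the unmeasured activation constants, and a synthetic-assay generator with
    a conjugate-blind readout convention for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    lhs,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
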