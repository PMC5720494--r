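Package: circacycle
Title: Simulation of the Coupled Mammalian Circadian Clock and Cell Cycle Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic simulation and analysis of a semi-quantitative
    ordinary differential equation model coupling the mammalian circadian
    core-clock (Bmal, Per, Cry, Rev-Erb, Ror and the CLOCK/BMAL and PER/CRY
    complexes) to cell-cycle regulators through the Ink4a/Arf locus: the
    INK4a/RB1/E2F1 pathway (module 1) and the ARF/MDM2/p53 pathway
    (module 2). Provides the 46-species, 170-parameter network with a
    compiled right-hand side, an intervention algebra (RAS activity via the
    ktt factor, Ink4a/Arf knockout, Bmal1 knockdown, module decoupling,
    species clamping), limit-cycle and transient period estimation,
    circadian-time phase mapping, cosinor and polynomial fitting, parameter
    control-coefficient analysis, dose-response and onset scans, model
    calibration against period and phase constraints, seeded synthetic
    rhythmic-trace generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
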