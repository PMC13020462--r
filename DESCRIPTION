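Package: thoraximp
Title: Finite-Element Tetrapolar Bioimpedance Modelling of Pulmonary Fluid
    Accumulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward modelling of tetrapolar (four-electrode) transfer
    impedance measurements on the human thorax for monitoring pulmonary
    fluid accumulation.  Provides a parametric synthetic thorax (torso,
    lungs, heart, ribs, airways, gravity-pooled fluid regions, surface
    electrode arrays), a deterministic graded tetrahedral mesher, a
    quasi-static conduction finite-element solver with terminal
    (equipotential, fixed total current) electrode conditions,
    reciprocity-based volume impedance density and regional sensitivity
    analysis, and experiment drivers for vertical electrode sweeps,
    fluid-volume sweeps, frequency sweeps and mesh convergence studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
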