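Package: carnmr
Title: Conformation-Activity Relationship Analysis from NMR-Detected
    Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies two-state (transcriptionally repressive vs. active)
    protein conformational ensembles from 2D [1H,15N] NMR peak volumes and
    relates the ensemble position to graded ligand efficacy across a ligand
    series. Provides 2D peak picking, Lorentzian lineshape fitting and
    elliptical volume integration, assignment transfer by minimum chemical
    shift perturbation, population-weighted chemical-shift statistics,
    Bloch-McConnell two-site exchange lineshape simulation, pharmacology
    curve fitting (three-parameter sigmoidal dose-response, one-site total
    binding with a shared fixed Bmax, coregulator bias factors, ddCt
    relative expression), Spearman conformation-activity correlation with
    an exact permutation option, Kabsch C-alpha superposition of crystal
    structures, and a synthetic-data generator that emulates the full
    study design with per-ligand ground-truth state populations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
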