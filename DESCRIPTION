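Package: mitoquant
Title: Quantification Pipelines for Mitochondrial Transplantation Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-organelle and plate-level quantification for mitochondrial
    transplantation experiments. Provides a synthetic-microscopy generator with
    ground-truth manifests (calcein time-lapses, transmitted-light z-stacks,
    two-channel GFP/TMRE uptake fields, plate-reader exports), particle
    detection and background-subtracted intensity traces, decision rules for
    mitochondrial permeability transition (calcein release), swelling
    (transmittance morphometry), membrane-potential polarization and electron
    transport chain response, intensity-ratio counting of internalized
    mitochondria, plate-assay normalization with linear calibration curves and
    dose arithmetic, and one-way ANOVA with the Student-Newman-Keuls post hoc
    procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
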