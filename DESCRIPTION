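Package: pelvigrade
Title: Interpretable Pelvic Fracture Severity Grading from CT Fracture Detections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Grades pelvic trauma severity on the Tile AO/OTA scale from
    per-slice fracture detections on CT. Implements augmentation-based
    self-ensembling: detections from mildly augmented copies of a scan are
    fused into 3D findings whose confidence is the fraction of augmented
    scans in which they appear. A boolean Bayesian network over fracture
    types, patient age, and rotational/translational instability infers the
    Tile grade and retrieves low-confidence fractures that are likely to
    co-occur with the high-confidence findings. Includes CT preprocessing
    (Hounsfield windowing, axial maximum intensity projections), a synthetic
    cohort and detector simulator, and an evaluation harness with ROC-AUC,
    Cohen's kappa, cross-validation, and threshold sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    RNifti,
    stats,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
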