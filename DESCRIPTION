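Package: teaspec
Title: Multispectral Tea Canopy Phenotyping, Cultivar Classification and
    Germination-Period Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for identifying tea (Camellia sinensis)
    cultivars and their germination period from five-band multispectral canopy
    imagery (blue 475 nm, green 560 nm, red 668 nm, red-edge 717 nm, near
    infrared 840 nm).  Provides reference-panel radiometric calibration,
    ExGR/Otsu canopy segmentation, an 86-indicator feature registry (colour
    values and indices, GLCM and LBP texture statistics, band reflectances and
    50 vegetation indices), UVE-PLS and LASSO feature screening with VIP
    importance scores, support-vector-machine classification with genetic
    algorithm, particle swarm and grey wolf hyperparameter optimisation, and
    Fisher discriminant analysis of germination period.  A seeded synthetic
    multispectral canopy generator makes every stage testable without field
    imagery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    tools,
    utils,
    e1071,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
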