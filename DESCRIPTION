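Package: condyseg
Title: Region-Growing Segmentation of Mandibular Condyles from CBCT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic segmentation of mandibular condyles from cone-beam
    computed tomography (CBCT) volumes using seeded connected-component region
    growing with locally varying, per-slice interpolated intensity thresholds.
    Includes slice-level post-processing corrections, morphological opening to
    sever spurious condyle-fossa connections, surface mesh extraction with
    low-shrinkage smoothing, validation statistics (Dice coefficient, surface
    distance maps, two-way absolute-agreement intraclass correlation), a
    synthetic CBCT condyle phantom generator with simulated observers, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    Matrix,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
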