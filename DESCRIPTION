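Package: regiopd
Title: Regioselectivity Prediction for Directing-Group-Assisted Pd C-H Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts the regioselectivity of palladium-mediated C-H activation
    proceeding through the concerted metalation-deprotonation mechanism.
    Candidate palladacycle intermediates are enumerated from a substrate SMILES
    by pairing sp2 C-H bonds with lone-pair directing heteroatoms, screened by
    2D ring-angle geometry or by a force-field ring-strain criterion for remote
    directing groups, deduplicated by graph symmetry, embedded as 3D
    substrate-Pd(OAc) complexes, and ranked by conformer-ensemble energies from
    a pluggable engine (deterministic mock, UFF, or external GFN1-xTB / DFT
    single points). A fast lookup-table predictor based on priority-sorted
    SMARTS patterns with tabulated directing-group strengths is also provided.
    Cheminformatics primitives are delegated to RDKit through a bundled Python
    backend.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with the rdkit package
Config/testthat/edition: 3
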