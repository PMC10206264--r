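Package: bindsight
Title: Binding-Model Analysis and Combinatorial R-Group Design from
    Protein-Ligand Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-state binding free energy analysis of protein-ligand
    molecular dynamics trajectories and structure-guided inhibitor design.
    Implements hydrogen-bond occupancy and geometric contact analysis,
    MM/GBSA binding free energies with an OBC-II generalized Born solvent
    model, Shrake-Rupley surface areas and quasi-harmonic entropies,
    per-residue energy decomposition with backbone/side-chain splits,
    trajectory clustering with medoid receptor extraction, four-region
    combinatorial R-group library enumeration with ensemble (minimum over
    receptor conformations) score aggregation, and a seeded synthetic-data
    generator with planted ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
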