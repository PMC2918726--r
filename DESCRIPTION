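Package: ensmap
Title: Ensemble Fragment-Based Hot-Spot Mapping of Receptor Conformers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for discovering non-orthosteric (putative
    allosteric) binding hot spots on receptor structures from a conformational
    ensemble. Reduces a multi-model PDB ensemble to representative structures
    by Kabsch superposition, pairwise RMSD and GROMOS (Daura) neighbour
    clustering; maps each representative with a library of 16 rigid organic
    probe fragments docked exhaustively on precomputed Lennard-Jones and
    electrostatic energy grids; aggregates low-energy probe pose clusters into
    ranked consensus sites; and profiles per-residue probe contacts across the
    ensemble to rank, classify (orthosteric versus non-orthosteric) and group
    residues into candidate allosteric sites. Includes a synthetic
    pseudo-receptor generator that plants ground-truth-labelled orthosteric
    and transiently open allosteric pockets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
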