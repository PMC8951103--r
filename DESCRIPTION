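Package: fragshare
Title: Fragment Contribution Analysis and Group Efficiency for Ligand-Receptor Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Partitions the binding affinity of a ligand-receptor complex into
    additive fragment contributions by scoring hydrogen-capped fragments of the
    ligand in place, at their exact coordinates in the complex (the reverse
    fragment-based drug discovery scheme). Per-fragment stakeholder shares are
    scaled by the molecular interaction energy and converted into group
    efficiencies, the fragment-level analog of ligand efficiency. Includes PDB
    and PDBQT readers and writers, a built-in empirical pairwise scoring
    function with vina and vinardo parameter sets, an adapter contract for
    external score-only programs, docking-pose selection by anchor-fragment
    RMSD against a crystal reference, multi-backend consensus reporting, and a
    synthetic fixture generator with analytically known scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
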