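Package: metalff
Title: Bonded-Model Force-Field Parametrization and Conformer Analysis
    for Metal Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated generation of molecular-mechanics parameters for
    metal-containing (and metal-free) complexes and analysis of their
    conformer ensembles.  Perceives bonds from scaled van der Waals radii,
    fragments systems by depth-first search with the metal kept separate,
    derives harmonic bond and angle force constants for the metal center
    from a Cartesian Hessian by the Seminario method, fits restrained
    electrostatic-potential (RESP) charges on Merz-Kollman shells, writes
    Amber frcmod and TRIPOS mol2 parameter files, packs explicit-solvent
    simulation boxes with counterions, emits equilibration and production
    molecular-dynamics input decks, and clusters trajectories by
    heavy-atom RMSD with energy-ranked representatives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), cluster, mclust, withr
Config/testthat/edition: 3
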