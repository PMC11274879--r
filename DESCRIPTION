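Package: abetadmd
Title: Event-Driven Discrete Molecular Dynamics of Coarse-Grained
    Amyloid-Beta Oligomer Formation
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An event-driven discrete molecular dynamics (DMD) simulator for
    a four-bead-per-residue coarse-grained model of amyloid-beta (Abeta)
    peptides with a hydropathy-based implicit solvent, together with the
    analysis pipeline used to characterise peptide self-assembly: oligomer
    size distributions (molar and mass-weighted, with SEM), secondary
    structure propensities from a dihedral/hydrogen-bond classifier,
    intra- and intermolecular residue contact maps, hydrophobic
    solvent-accessible surface area, end-to-end geometry, two-dimensional
    potential-of-mean-force landscapes, and fractal shape statistics from
    principal moments of inertia.  Synthetic-data generators with known
    ground truth make every analysis stage testable without long
    simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    graphics,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
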