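Package: metabind
Title: Ligand Binding-Mode Determination by Funnel-Restrained
    Multiple-Walker Metadynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a desk-scale, end-to-end protocol for locating
    the preferred binding mode of a small ligand in a receptor pocket:
    well-tempered metadynamics along a single binding collective
    variable (the z-component of a receptor-anchor-to-ligand-nitrogen
    distance), funnel and harmonic-wall restraints with analytic
    gradients, shared-bias multiple walkers, free-energy reconstruction
    from deposited Gaussian hills, extraction of frames around the
    free-energy minimum, hierarchical agglomerative clustering on the
    unfitted ligand heavy-atom RMSD with population ranking, and
    unbiased Langevin refinement of cluster representatives with
    convergence diagnostics.  Ships a synthetic-system generator
    (analytic double wells with known free-energy differences, a 3D
    pocket-plus-channel binding landscape with a planted bound pose,
    and planted multi-mode conformational ensembles) so every stage of
    the protocol can be validated against ground truth.  Reads and
    writes PLUMED-dialect HILLS and COLVAR files and multi-frame
    XYZ/PDB trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
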