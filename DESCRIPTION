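Package: cgmotor
Title: Coarse-Grained Model Building for Molecular Motors and Switches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for building and validating coarse-grained
    (CG) bonded models of molecular motors and switches in the Martini
    tradition. Forward-maps atomistic conformer ensembles onto CG beads
    (including virtual sites), derives bonded potentials by Boltzmann
    inversion with iterative distribution matching against a built-in
    Metropolis Monte Carlo sampler, and validates models with mean-absolute-
    error statistics on bond/angle/dihedral distributions and solvent-
    accessible surface area. Includes free-energy estimators (thermodynamic
    integration, Bennett acceptance ratio, WHAM with bootstrap errors),
    octanol-water log P assembly, toy drivers for enforced rotation and
    topology switching, a GROMACS-dialect topology (.itp) and coordinate
    (.gro/XYZ) reader/writer subset, and seeded synthetic-fixture generators
    with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
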