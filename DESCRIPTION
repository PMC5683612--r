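Package: cgkit
Title: Coarse-Grained Protein Interaction Scaling and Dimerization Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for rescaling protein-protein Lennard-Jones interactions
    in Martini-style coarse-grained force fields and for analysing the
    resulting simulations. Reads and writes GROMACS-dialect nonbonded
    parameter tables (sigma-epsilon or C6/C12 form), GRO/PDB coordinates and
    XVG time series; applies uniform or water-contact-restricted epsilon
    scaling with a repulsive floor; estimates potentials of mean force from
    umbrella-sampling windows by the weighted histogram analysis method with
    Bayesian bootstrap errors; converts free-energy profiles into
    two-dimensional association constants and dimerization free energies;
    computes transmembrane-dimer structure metrics (backbone RMSD, helix
    crossing angle, inter-peptide contacts) and oligomer cluster-size
    statistics under periodic boundaries. A synthetic-fixture generator
    provides Martini-like interaction matrices, ideal coarse-grained helices
    and dimers, Metropolis-sampled umbrella windows from known free-energy
    profiles, and peptide configurations with known cluster structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    graphics,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
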