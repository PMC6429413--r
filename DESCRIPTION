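Package: hingewatch
Title: Domain-Motion Analysis of Multidomain Proteins by Elastic Network
    Modes, Essential Dynamics and Near-Attack Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising collective domain motions in
    multidomain proteins such as the dimeric triokinase/FMN cyclase fold.
    Implements anisotropic elastic-network normal-mode analysis with
    mass-weighted eigenanalysis and trivial-mode handling, thermal-ensemble
    and harmonic-trajectory generation from normal modes, essential-dynamics
    principal component analysis of trajectories, cross-system mode
    comparison by eigenvector inner products after reduction to a common
    atom set, rigid-body superposition with RMSD/RMSF mobility profiling,
    and active-site closure plus near-attack-conformation geometry scans
    (O...P distance and in-line O...P-O angle censuses). A deterministic
    synthetic-structure generator emulating an elongated two-domain dimer
    makes the whole pipeline runnable and testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
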