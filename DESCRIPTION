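Package: diabatmd
Title: Diabatic Excited-State Molecular Dynamics with Delta-SCF and a
    Polarizable Embedding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Desk-scale excited-state Born-Oppenheimer molecular dynamics on
    single-determinant (Delta-SCF) surfaces.  Provides restricted and
    unrestricted Hartree-Fock SCF with DIIS over two interchangeable
    integral providers (a minimal s-type Gaussian backend and a
    Pariser-Parr-Pople pi-electron model), excited-state SCF via the
    initial maximum overlap method (iMOM) and state-targeted energy
    projection (STEP) with diabatic state tracking, an AMOEBA-style
    polarizable environment (permanent multipoles through quadrupoles and
    Thole-damped induced point dipoles solved by preconditioned conjugate
    gradient) coupled self-consistently and state-specifically to the QM
    density, Grassmann-manifold density-matrix extrapolation of open-shell
    SCF guesses along a trajectory, a velocity-Verlet integrator with the
    Bussi stochastic velocity-rescaling thermostat, and trajectory
    analysis for proton-coupled electron transfer (proton-transfer
    coordinates, event detection, dipole-based charge-transfer state
    assignment, conformer classification and ensemble statistics).
    Includes seeded generators for a donor-bridge-acceptor PCET toy system
    with a polarizable environment shell.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
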