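Package: sqdbinder
Title: Sample-Based Quantum Diagonalization for Supramolecular Binding Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A fully classical implementation of the sample-based quantum
    diagonalization (SQD) workflow for computing supramolecular binding
    energies of noncovalent dimers within an active space.  Provides an
    FCIDUMP reader/writer and geometry tools, a determinant-basis
    configuration-interaction engine (Slater-Condon matrix elements,
    Davidson eigensolver, occupation numbers, Hamiltonian variance), the
    truncated local unitary cluster Jastrow (LUCJ) ansatz initialized from
    CCSD doubles amplitudes, a synthetic sampling device with
    particle-number-breaking bit-flip noise, self-consistent configuration
    recovery over batch subspaces, energy-variance extrapolation, and
    bound/unbound binding-energy curves along a dissociation coordinate.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
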