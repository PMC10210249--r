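Package: rcadc
Title: Reduced-Cost CVS-ADC(2) Simulation of K-Edge Core Excitations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes X-ray absorption (K-edge) core-excitation energies and
    oscillator strengths for closed-shell molecules with the strict second-order
    algebraic-diagrammatic construction method under the core-valence separation
    (CVS-ADC(2)), using density-fitted two-electron integrals throughout.  A
    reduced-cost mode compresses the virtual orbital space with state-specific
    frozen virtual natural orbitals built from a state-averaged MP2/CVS-CIS(D)
    density, and compresses the auxiliary basis with natural auxiliary functions
    obtained from the singular structure of the three-center integral tensor.
    Includes a self-contained Gaussian-integral and restricted Hartree-Fock
    backend, a nonlinear (omega-dependent) Davidson/DIIS eigensolver for the
    folded singles problem, dipole-length oscillator strengths, small-molecule
    fixtures, brute-force validation oracles, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
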