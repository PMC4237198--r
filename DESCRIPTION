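Package: chargecorr
Title: Finite-Size and Effective-Electrostatics Corrections to Charging Free Energies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns raw charging free energies of charged guest molecules, computed
    from molecular dynamics simulations under periodic boundary conditions with
    lattice-summation or Barker-Watts reaction-field electrostatics, into
    methodology-independent values. Implements the four correction terms of the
    underlying thermodynamic cycle (spurious solvent polarization and solvent-model
    permittivity, atom- versus molecule-based potential summation, effective
    guest-host direct interactions, and excluded-pair interactions) with a
    finite-difference Poisson solver for heterogeneous dielectrics under periodic
    and nonperiodic boundary conditions, an FFT Green's-function solver for
    truncated interaction kernels, Ewald evaluation of the periodic Coulomb
    Green's function, trapezoidal thermodynamic integration with block-averaging
    errors, synthetic buckyball guest-host fixtures, and bookkeeping for corrected
    charging contributions to binding free energies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, bio3d
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
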