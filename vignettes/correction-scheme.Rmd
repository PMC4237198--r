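---
title: "Correcting charging free energies for finite-size and effective-electrostatics artifacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting charging free energies for finite-size and effective-electrostatics artifacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chargecorr)
```

## The problem

The charging free energy of an ion — the reversible work of scaling its
partial charges from zero to their full values at fixed van der Waals
envelope — is a central ingredient of binding free energies whenever the
bound and unbound species differ in net charge.  Computed from molecular
dynamics simulation, it is *methodology dependent*: a lattice-summation
(LS, Ewald/P3M-type) treatment of electrostatics makes the ion interact
with an infinite lattice of its own periodic copies, a cutoff scheme with
Barker-Watts reaction-field correction (BM) discards explicit interactions
beyond the cutoff sphere, and the water model's dielectric permittivity
(66.6 for SPC) differs from the experimental one (78.4).  Raw charging
free energies of the same ion in the same solvent can differ by tens of
kJ/mol between schemes and box sizes.

This package implements a correction scheme that turns such raw values
into methodology-independent ones,

$$\Delta G_{\mathrm{cor}} = \Delta G_{\mathrm{raw}}
  + \Delta G_{\mathrm{pol}} + \Delta G_{\mathrm{sum}}
  + \Delta G_{\mathrm{hs}} + \Delta G_{\mathrm{excl}},$$

and assembles corrected charging contributions to binding free energies
for a benchmark family of host-guest systems: an artificial C60 cage
(all bonds 0.2 nm), bare or functionalized with a formamide, methylammonium
or formate group (CAPO/CHB/CPOS/CNEG), binding a methylammonium (MAM, +1 e)
or acetate (ACE, -1 e) guest.

## The four correction terms

**Polarization and permittivity, `dG_pol`.**  The difference of two
continuum-electrostatics charging calculations: one for a macroscopic
nonperiodic Coulombic system at the experimental permittivity (CB,
eps = 78.4) and one reproducing the simulated conditions (LS or BM under
periodic boundary conditions at the model permittivity, eps = 66.6).
Both are evaluated on the same solute configuration with the same grid
resolution, per charge state, as
$\int_0^1 \sum_i q_i\,\phi_{\mathrm{env}}(i;\lambda)\,d\lambda$, where the
environment-generated potential is the heterogeneous-dielectric solution
minus a same-grid, same-scheme vacuum solve of the identical charge set.
Using the *same scheme* for the vacuum reference is essential: it cancels
the grid self-energy and all intramolecular and direct guest-host terms,
and it removes the bare interaction of the guest with its own periodic
copies — the self term that the simulated Hamiltonian excludes as well.
With an ideal-Coulomb (nonperiodic) reference instead, the correction for
a single cation in water comes out with the wrong sign.

**Summation scheme, `dG_sum`.**  Simulations accumulate the
solvent-generated potential at the ion atom by atom (P-summation); a
physically meaningful potential sums molecule by molecule (M-summation).
The difference is driven by the quadrupole-moment trace of the water
model relative to its van der Waals site, $\gamma_s$ (0.0082 e nm$^2$ for
SPC).  The correction follows from integrating the water-density-weighted
Laplacian of the effective pair potential.  For LS,
$\nabla^2 \psi_{\mathrm{LS}}$ has (besides the point singularity) only the
uniform-background term, giving

$$\Delta G_{\mathrm{sum}}^{\mathrm{LS}}
  = -\frac{2\pi}{3}\, k_C\, Q_G \gamma_s \frac{N_w}{L^3}.$$

For the BM form, the quadratic reaction-field term contributes a
cutoff-sphere population term ($3 C_{\mathrm{RF}} \langle N_v\rangle /
(4\pi R_C^3)$, with $\langle N_v\rangle$ the mean number of waters inside
the cutoff sphere) and the truncation of the potential at $R_C$
contributes a surface term ($(1 - C_{\mathrm{RF}})\, N_w / L^3$).  With
bulk-density $\langle N_v\rangle$ the two forms agree closely, as they
must (the derivation is checked in the test suite); both population terms
are individually switchable for comparison with earlier variants.

**Guest-host interactions, `dG_hs`.**  In-host raw values contain
guest-host direct electrostatics evaluated with the effective scheme
under periodicity; the correction replaces them by nonperiodic Coulomb
interactions, $\Delta G_{\mathrm{hs}} = \Delta G_{GH}^{\mathrm{CB}} -
\Delta G_{GH}^{\mathrm{eff}}$, each a trapezoidal thermodynamic
integration over per-lambda configuration ensembles.  Because the guest
charges scale linearly with lambda, a rigid complex reduces this to a
full-charge energy difference.  It vanishes for the uncharged CAPO cage,
is positive for like-charged guest-host pairs and negative for
oppositely charged ones.

**Excluded pairs, `dG_excl`.**  Covalently excluded pairs (first and
second neighbours) do not interact via 1/r, but they do feel the
remainder of the effective scheme.  The interaction function relevant
here is additionally exempt of its self term, i.e. the kernel is
$(\psi_{\mathrm{eff}} - 1/r)$ minus its $r \to 0$ limit: for BM exactly
the reaction-field curvature $C_{\mathrm{RF}} r^2 / (2 R_C^3)$
(box-size independent), for LS the curvature of the periodic Green's
function (of order $r^2/L^3$, decaying with box size).  Retaining the
constant offset instead would predict corrections of tens of kJ/mol for
any guest whose excluded-pair charge products do not cancel, two orders
of magnitude above the sub-kJ/mol values these corrections are known to
take; the limit-subtracted kernel reproduces both the magnitude and the
box-size behaviour.  The lambda integral is analytic (both charges scale
with lambda), so the correction is minus the full-charge excluded-pair
energy with that kernel.

## Numerical machinery

**Pair functions.**  `psi()` evaluates the three effective interaction
functions: plain Coulomb; the Barker-Watts form
$1/r + C_{\mathrm{RF}} r^2/(2R_C^3) - (1 + C_{\mathrm{RF}}/2)/R_C$
(exactly zero at and beyond the cutoff), with
$C_{\mathrm{RF}} = (2\varepsilon_{\mathrm{RF}} - 2)/(2\varepsilon_{\mathrm{RF}} + 1)$,
the zero-ionic-strength constant of GROMOS-style implementations (the
source publications do not print it); and the periodic Coulomb Green's
function by Ewald summation (alpha = 3.5/L, reciprocal shells to
|n|^2 <= 64, parameters exposed), never including a self term.  The
Ewald evaluation is checked against an independently coded naive
double-loop Ewald sum at different splitting parameters and against the
analytic $r \to 0$ limit $-2.837297/L$ (the cubic-lattice self
constant).

**Finite-difference Poisson solver.**  Symmetric 7-point stencil on a
cubic grid, heterogeneous permittivity, preconditioned conjugate
gradients (Jacobi preconditioner).  Atom charges are spread with
trilinear (cloud-in-cell) weights and potentials interpolated back with
the same weights.  Face permittivities use a fraction-weighted harmonic
mean: each grid edge is sampled at three points for overlap with the
solute envelope and the face value is
$1/(f + (1-f)/\varepsilon_s)$ — positioning the dielectric boundary with
sub-grid accuracy (a plain node-based harmonic mean biases a 0.2 nm Born
radius by about 5% at 0.05 nm spacing; the edge-fraction form is within
about 1%).  Under PBC the system carries a uniform neutralizing
background and the solution is gauged to zero mean; under NPBC the
boundary faces are held at the solvent-screened Coulomb potential of the
charge set.  Convergence is declared when the grid free energy changes
by less than 0.01 kJ/mol between checks and the relative residual is
below 1e-5 (the solver literature this follows does not state its
threshold; these are this package's own choices).

**FFT Green's-function solver.**  For kernels that are not the inverse
of a differential operator (the truncated BM form), the potential is a
kernel convolution evaluated by FFT.  The periodic Coulomb kernel is
defined spectrally as $4\pi k_C / k_d^2$ with $k_d^2$ the eigenvalues of
the *discrete* 7-point Laplacian, making the homogeneous FFT solve the
exact inverse of the FD stencil — the two solvers then agree to machine
precision on homogeneous systems, and short-range discretization errors
are shared between kernels.  The BM (and in-box Coulomb) kernels are the
spectral kernel plus the FFT of their bounded real-space difference from
the periodic Coulomb function.  Heterogeneous permittivity enters
through the bound-charge self-consistency $(I - BG)\,q_b = BGq$, solved
matrix-free with restarted GMRES; the operator's spectrum is clustered
in $[1, \varepsilon]$, and simpler fixed-point or BiCGstab iterations
were found to diverge or stagnate at water-like permittivity contrast.
The BM continuum charging free energy combines the two solvers,
$\Delta G_{\mathrm{BM}} = \Delta G^{\mathrm{FD}}_{\mathrm{LS}} +
\Delta G^{\mathrm{FFT}}_{\mathrm{BM}} -
\Delta G^{\mathrm{FFT}}_{\mathrm{LS}}$, each term referenced against its
own same-solver vacuum solve so that grid-discretization and
boundary-smoothing errors cancel between terms.

**Radii.**  The solute envelope uses per-atom radii equal to the
distance at the Lennard-Jones minimum to a water oxygen minus the water
probe radius (0.14 nm); polar hydrogens get 0.05 nm.  The LJ-minimum
table shipped as a default holds stand-in values of realistic magnitude
and is fully configurable — as are the guest/host partial charge sets,
which sum exactly to the nominal net charges (+1 MAM, -1 ACE, 0/+1/-1
for the CHB/CPOS/CNEG groups) but are *not* force-field values (the
original force-field topologies are not assumed available).

**Thermodynamic integration.**  Trapezoidal rule on the standard
11-point lambda grid (arbitrary grids accepted); per-lambda statistical
errors combine through the trapezoid weights in quadrature, treating
block-averaged per-lambda estimates as independent.  Block averaging
uses power-of-two block sizes and returns the first plateau (successive
estimates within 5%), falling back to the largest-block estimate.

## The synthetic fixtures and what the tests show

`build_buckyball()` places 60 carbons on an exact truncated-icosahedron
hull (90 bonds, all equal to the requested 0.2 nm; all vertices
equidistant from the centroid), appends the functional groups for
CHB/CPOS/CNEG, and `build_complex()` centres the guest's charge-bearing
atom (MAM nitrogen, ACE carboxylate carbon) at the cage centre of mass,
with an optional seeded random rigid displacement.  All builders are
pure functions of (recipe, seed).

The fixtures emulate the benchmark systems' geometry, connectivity and
net charges, but not configurational sampling: there is no explicit
water, no thermal motion, and the guest sits at the cage centre rather
than sampling poses (pose fluctuations are known to contribute little to
the continuum corrections for these rigid cavities).  Passing tests
therefore validate the correction machinery — closed forms, solvers,
bookkeeping — on exactly specified inputs; they do not re-derive the
published raw simulation values, which would require the original
force-field topologies and sampled trajectories.  For the same reason
the published per-system polarization corrections are not
desk-reproducible and are exercised through their printed values
(shipped as plain-text reference tables) plus solver-level oracles: the
Born closed form within 2% at 0.05 nm spacing, the cubic-lattice
(Wigner) self term within 0.5%, and single-cation LS polarization
corrections of the right sign and magnitude.

## Problem sizes and numerical choices

Default production spacing for continuum solves is 0.02 nm; the test
suite and the examples run at 0.05-0.1 nm, where the Born oracle is
reproduced within 1-2% and a full single-ion `dG_pol` takes seconds.
The lambda grid for continuum integration defaults to the two
end points — exact here, because the continuum response is linear in
lambda — while simulation-derived series use the 11-point grid.  The
rmsd statistics of the reporting module use the divisor-N convention
(root-mean-square deviation about the mean), which is the convention
that reproduces the published spreads from the published per-row values;
report tables round half away from zero to 0.1 kJ/mol.

The neglected direct-interaction term of the underlying cycle
(proportional to the guest-to-box volume ratio) is outside scope, as are
the van der Waals creation step, molecular (reentrant) surfaces, ionic
strength, and any MD propagation machinery.

## Known limitations

* The guest/host charge sets and LJ table are declared stand-ins;
  quantitative agreement with published per-system corrections is not a
  goal of the fixtures.
* The FFT solver's heterogeneous path assumes the permittivity map is
  1 inside the envelope and a single solvent value outside (matching the
  envelope model); arbitrary multi-dielectric maps would need a
  preconditioner for the bound-charge solve.
* The NPBC boundary potential is the solvent-screened Coulomb field of
  the charge set; for solutes approaching the domain boundary a larger
  domain must be chosen by the caller.
* `estimate_n_in_cutoff()` counts water oxygens with the minimum-image
  convention and assumes cubic boxes, as does everything else in the
  package.
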