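#' Assign continuum radii from a Lennard-Jones minimum-distance table
#'
#' The van der Waals envelope used in the continuum solves is built from
#' per-atom radii equal to the distance at the Lennard-Jones minimum
#' between the atom type and the water oxygen, reduced by the water probe
#' radius (0.14 nm).  Polar hydrogens are treated separately and assigned a
#' fixed radius of 0.05 nm.
#'
#' @param s a \code{solute_structure}
#' @param lj_table named vector of LJ-minimum distances to water oxygen per
#'   element label, nm (default \code{default_lj_minimum_table()})
#' @return the structure with its \code{radius} column filled
#' @export
#' @examples
#' s <- assign_radii(build_buckyball(fixture_recipe(host = "CAPO")))
#' unique(s$atoms$radius)  # 0.27
assign_radii <- function(s, lj_table = default_lj_minimum_table()) {
  pc <- phys_constants()
  a <- s$atoms
  for (i in seq_len(nrow(a))) {
    if (a$is_polar_hydrogen[i]) {
      a$radius[i] <- pc$polar_H_radius
      next
    }
    el <- a$element[i]
    if (!el %in% names(lj_table))
      stop("element '", el, "' missing from the LJ-minimum table")
    r <- lj_table[[el]] - pc$water_radius_probe
    if (r <= 0)
      stop("LJ-minimum distance for '", el,
           "' is below the water probe radius; resulting radius invalid")
    a$radius[i] <- r
  }
  s$atoms <- a
  s
}

# one continuum charging TI:  dG = int_0^1 sum_i q_i phi_env(i;lambda)
# with phi_env = phi(full solve) - phi(same charges, eps = 1 everywhere,
# same boundary conditions / kernel, same grid and solver).  Using the
# same scheme for the vacuum reference subtracts, besides the grid
# self-energy and all intramolecular terms, the bare interaction of the
# guest with its own periodic copies -- the "self term" that the simulated
# Hamiltonian excludes as well -- so only the environment-mediated
# (solvent-polarization) response remains.
continuum_ti <- function(s, L, spacing, eps_solvent, boundary, solver,
                         kernel = NULL, spec = NULL,
                         lambdas = c(0, 1), tol_energy = 0.01) {
  a <- s$atoms
  gi <- which(a$group == "guest")
  if (!length(gi)) gi <- seq_len(nrow(a))   # single-solute charging
  qfull <- a$charge
  integrand <- vapply(lambdas, function(lam) {
    q <- qfull
    q[gi] <- lam * q[gi]
    if (all(q == 0)) return(0)
    gfull <- dielectric_grid(s, L, spacing, eps_solvent, boundary,
                             charges = q)
    gref <- dielectric_grid(s, L, spacing, eps_solvent = 1,
                            boundary = boundary, charges = q)
    if (solver == "fd") {
      phi_full <- solve_poisson_fd(gfull, tol_energy = tol_energy)
      phi_ref <- solve_poisson_fd(gref, tol_energy = tol_energy)
    } else {
      phi_full <- solve_poisson_fft(gfull, kernel = kernel, spec = spec)
      phi_ref <- solve_poisson_fft(gref, kernel = kernel, spec = spec)
    }
    env <- potential_at_sites(gfull, phi_full, gi) -
      potential_at_sites(gref, phi_ref, gi)
    sum(qfull[gi] * env)
  }, numeric(1))
  sum(trapezoid_weights(lambdas) * integrand)
}

#' Continuum-electrostatics charging free energy
#'
#' Charging free energy of the guest (or of a lone solute) in a dielectric
#' continuum, for one of the three electrostatic representations:
#' \describe{
#'   \item{CB}{macroscopic nonperiodic Coulomb system at the experimental
#'     solvent permittivity (78.4); finite-difference solve under NPBC.}
#'   \item{LS}{periodic lattice-summation system at the solvent-model
#'     permittivity (66.6); finite-difference solve under PBC with
#'     neutralizing background and zero-mean gauge.}
#'   \item{BM}{cutoff-truncated Barker-Watts reaction-field system at the
#'     solvent-model permittivity; evaluated as a finite-difference PBC
#'     solve plus an FFT kernel correction,
#'     dG_FD(LS) + dG_FFT(BM) - dG_FFT(LS), pairing each solver with its
#'     own in-box Coulomb reference so that grid-discretization and
#'     boundary-smoothing errors cancel between terms.}
#' }
#' The environment-generated potential at each guest site is the full
#' heterogeneous-dielectric solution minus a same-grid, same-scheme vacuum
#' (eps = 1) reference of the identical charge set, which cancels the grid
#' self-energy, removes all direct intramolecular and guest-host terms,
#' and removes the bare periodic self-interaction (the self term the
#' simulated Hamiltonian excludes); the lambda integral is evaluated with
#' the trapezoidal rule (the continuum response is linear in lambda, so
#' the default two-point grid is exact).
#'
#' @param s a \code{solute_structure} with radii assigned
#' @param spec a \code{scheme_spec}; supplies box edge, permittivities,
#'   cutoff and grid spacing
#' @param scheme "CB", "LS" or "BM"
#' @param spacing grid spacing override, nm
#' @param lambdas lambda grid for the thermodynamic integration
#' @return charging free energy, kJ/mol
#' @export
charging_free_energy_continuum <- function(s, spec,
                                           scheme = c("CB", "LS", "BM"),
                                           spacing = spec$spacing,
                                           lambdas = c(0, 1)) {
  scheme <- match.arg(scheme)
  L <- spec$box_edge_L
  if (!is.finite(L)) stop("spec must carry a box edge length")
  if (scheme == "CB") {
    continuum_ti(s, L, spacing, eps_solvent = spec$eps_experimental,
                 boundary = "NPBC", solver = "fd", lambdas = lambdas)
  } else if (scheme == "LS") {
    continuum_ti(s, L, spacing, eps_solvent = spec$eps_solvent_model,
                 boundary = "PBC", solver = "fd", lambdas = lambdas)
  } else {
    fd_ls <- continuum_ti(s, L, spacing,
                          eps_solvent = spec$eps_solvent_model,
                          boundary = "PBC", solver = "fd",
                          lambdas = lambdas)
    fft_bm <- continuum_ti(s, L, spacing,
                           eps_solvent = spec$eps_solvent_model,
                           boundary = "PBC", solver = "fft", kernel = "BM",
                           spec = spec, lambdas = lambdas)
    fft_ls <- continuum_ti(s, L, spacing,
                           eps_solvent = spec$eps_solvent_model,
                           boundary = "PBC", solver = "fft", kernel = "LS",
                           spec = spec, lambdas = lambdas)
    fd_ls + fft_bm - fft_ls
  }
}

#' Polarization / permittivity correction
#'
#' Correction for spurious solvent polarization around the charged guest
#' (periodicity or cutoff truncation) and for the inaccurate permittivity
#' of the solvent model:
#' \code{dG_pol = dG_CB(eps = 78.4, NPBC) - dG_X(eps = 66.6, PBC)},
#' the difference of two continuum-electrostatics charging calculations.
#'
#' @param s a \code{solute_structure} with radii assigned
#' @param spec \code{scheme_spec} of the simulated system
#' @param scheme effective scheme used in the simulation, "LS" or "BM"
#' @param spacing grid spacing, nm
#' @param lambdas lambda grid
#' @return correction in kJ/mol
#' @export
dG_pol <- function(s, spec, scheme = c("LS", "BM"), spacing = spec$spacing,
                   lambdas = c(0, 1)) {
  scheme <- match.arg(scheme)
  charging_free_energy_continuum(s, spec, "CB", spacing, lambdas) -
    charging_free_energy_continuum(s, spec, scheme, spacing, lambdas)
}
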