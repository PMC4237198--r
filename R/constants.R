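#' Physical constants and unit conventions
#'
#' All quantities in the package use nanometres for length, elementary
#' charges for charge and kJ/mol for energy.  In these units the Coulomb
#' prefactor 1/(4 pi eps0) evaluates to 138.9354578 kJ mol^-1 nm e^-2
#' (CODATA-consistent).
#'
#' @return Named list with elements
#'   \describe{
#'     \item{coulomb_factor}{1/(4 pi eps0), kJ mol^-1 nm e^-2}
#'     \item{avogadro}{Avogadro constant, mol^-1}
#'     \item{water_radius_probe}{estimate of the radius of a water molecule
#'       used to shrink Lennard-Jones envelope radii, nm}
#'     \item{polar_H_radius}{atomic radius assigned to polar hydrogens in
#'       continuum-electrostatics calculations, nm}
#'     \item{eps_spc}{relative dielectric permittivity of the SPC water model}
#'     \item{eps_water}{experimental relative permittivity of water at 300 K}
#'     \item{gamma_spc}{quadrupole-moment trace of the SPC water model
#'       relative to its single van der Waals site, e nm^2}
#'     \item{mu_spc}{molecular dipole moment of the SPC water model, e nm}
#'     \item{wigner_cubic}{self-term constant xi of a point charge in a cubic
#'       lattice with neutralizing background, dimensionless (times 1/L)}
#'   }
#' @export
#' @examples
#' phys_constants()$coulomb_factor
phys_constants <- function() {
  list(
    coulomb_factor     = 138.9354578,
    avogadro           = 6.02214076e23,
    water_radius_probe = 0.14,
    polar_H_radius     = 0.05,
    eps_spc            = 66.6,
    eps_water          = 78.4,
    gamma_spc          = 0.0082,
    mu_spc             = 2 * 0.41 * 0.1 * cos(0.5 * 109.47 * pi / 180),
    wigner_cubic       = -2.837297
  )
}

#' Barker-Watts reaction-field constant
#'
#' Zero-ionic-strength form used by GROMOS-style reaction-field
#' implementations, C_RF = (2 eps_RF - 2) / (2 eps_RF + 1).
#'
#' @param eps_rf relative permittivity of the dielectric continuum outside
#'   the cutoff sphere (66.6 for SPC water)
#' @return dimensionless constant in [0, 1)
#' @export
reaction_field_constant <- function(eps_rf) {
  stopifnot(is.numeric(eps_rf), eps_rf >= 1)
  (2 * eps_rf - 2) / (2 * eps_rf + 1)
}

# Distances at the Lennard-Jones minimum between solute atom types and the
# water oxygen, nm.  Stand-in values of the expected magnitude for a
# united-atom force field; configurable wherever they are consumed.
default_lj_minimum_table <- function() {
  c(C = 0.4100, CH2 = 0.4200, CH3 = 0.4250, N = 0.3700, O = 0.3500,
    OM = 0.3450, H = 0.2400)
}

#' Electrostatics scheme specification
#'
#' Describes how electrostatic interactions were (or are to be) evaluated:
#' \code{"LS"} for lattice summation over the periodic system, \code{"BM"}
#' for molecule-based cutoff truncation with Barker-Watts reaction-field
#' correction, or \code{"CB"} for plain Coulomb interactions in a
#' macroscopic nonperiodic system.
#'
#' @param scheme one of "LS", "BM", "CB"
#' @param box_edge_L cubic box edge length, nm (LS/BM)
#' @param n_water number of water molecules in the box
#' @param cutoff_RC cutoff radius, nm (BM only; default 1.4)
#' @param eps_solvent_model solvent-model permittivity used in PBC continuum
#'   solves (default 66.6)
#' @param eps_reaction_field reaction-field permittivity (BM; default 66.6)
#' @param eps_experimental experimental solvent permittivity used in the CB
#'   reference (default 78.4)
#' @param spacing grid spacing for continuum solves, nm
#' @param ewald_alpha_factor Ewald splitting parameter as a multiple of 1/L
#' @param ewald_kmax maximum squared reciprocal shell index |n|^2
#' @return object of class \code{scheme_spec}
#' @export
scheme_spec <- function(scheme = c("LS", "BM", "CB"),
                        box_edge_L = NA_real_, n_water = NA_integer_,
                        cutoff_RC = 1.4,
                        eps_solvent_model = 66.6, eps_reaction_field = 66.6,
                        eps_experimental = 78.4,
                        spacing = 0.05,
                        ewald_alpha_factor = 3.5, ewald_kmax = 64) {
  scheme <- match.arg(scheme)
  boundary <- if (scheme == "CB") "NPBC" else "PBC"
  if (scheme == "BM") {
    stopifnot(is.finite(box_edge_L), cutoff_RC > 0, cutoff_RC < box_edge_L)
  }
  if (scheme == "LS") stopifnot(is.finite(box_edge_L), box_edge_L > 0)
  structure(list(scheme = scheme, box_edge_L = box_edge_L,
                 n_water = n_water, cutoff_RC = cutoff_RC,
                 eps_solvent_model = eps_solvent_model,
                 eps_reaction_field = eps_reaction_field,
                 eps_experimental = eps_experimental,
                 boundary = boundary, spacing = spacing,
                 ewald_alpha_factor = ewald_alpha_factor,
                 ewald_kmax = ewald_kmax),
            class = "scheme_spec")
}

#' @export
print.scheme_spec <- function(x, ...) {
  cat("<scheme_spec> ", x$scheme, " (", x$boundary, ")",
      if (is.finite(x$box_edge_L)) sprintf(", L = %.3f nm", x$box_edge_L),
      if (x$scheme == "BM") sprintf(", R_C = %.2f nm", x$cutoff_RC),
      "\n", sep = "")
  invisible(x)
}
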