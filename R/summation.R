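#' Summation-scheme correction, lattice-summation case
#'
#' Corrects for the atom-based (P) summation of the solvent-generated
#' electrostatic potential implied by the simulation scheme, relative to a
#' proper molecule-based (M) summation.  For a lattice-summation scheme the
#' correction is
#' \deqn{dG_sum = - Q_G gamma_s N_w / (6 eps0 L^3)}
#' i.e. \code{-(2 pi / 3) k_C Q_G gamma_s N_w / L^3} in package units:
#' negative for cations, positive for anions.
#'
#' @param guest_net_charge Q_G, e
#' @param n_water number of water molecules in the box
#' @param box_edge_L cubic box edge, nm
#' @param gamma_s quadrupole-moment trace of the water model relative to
#'   its van der Waals site, e nm^2 (default SPC, 0.0082)
#' @return correction in kJ/mol
#' @export
#' @examples
#' dG_sum_ls(1, n_water = 800, box_edge_L = 2.90)  # about -78.3
dG_sum_ls <- function(guest_net_charge, n_water, box_edge_L,
                      gamma_s = phys_constants()$gamma_spc) {
  stopifnot(gamma_s > 0)
  if (box_edge_L <= 0) stop("box edge must be positive")
  kc <- phys_constants()$coulomb_factor
  -(2 * pi / 3) * kc * guest_net_charge * gamma_s * n_water / box_edge_L^3
}

#' Summation-scheme correction, Barker-Watts reaction-field case
#'
#' For a molecule-based cutoff scheme with Barker-Watts reaction field the
#' P-vs-M summation correction follows from integrating the water-density-
#' weighted Laplacian of the effective pair potential: the quadratic
#' reaction-field term contributes a cutoff-sphere population term and the
#' truncation of the potential at R_C contributes a surface (box-density)
#' term,
#' \deqn{dG_sum = -(2 pi / 3) k_C Q_G gamma_s [ 3 C_RF <N_v> / (4 pi R_C^3)
#'   + (1 - C_RF) N_w / L^3 ]}
#' with \code{C_RF} the reaction-field constant for \code{eps_rf}.  Both
#' population terms can be switched off individually to compare with
#' earlier variants of the correction.
#'
#' @param guest_net_charge Q_G, e
#' @param n_in_cutoff average number of water molecules within the cutoff
#'   sphere, \code{<N_v>}
#' @param cutoff_RC cutoff radius, nm
#' @param eps_rf reaction-field permittivity (default 66.6)
#' @param n_water number of water molecules in the box
#' @param box_edge_L cubic box edge, nm
#' @param gamma_s water-model quadrupole-moment trace, e nm^2
#' @param include_sphere_term,include_box_term logical switches for the two
#'   population terms
#' @return correction in kJ/mol
#' @export
dG_sum_bm <- function(guest_net_charge, n_in_cutoff, cutoff_RC,
                      eps_rf = 66.6, n_water, box_edge_L,
                      gamma_s = phys_constants()$gamma_spc,
                      include_sphere_term = TRUE, include_box_term = TRUE) {
  if (missing(n_in_cutoff) || is.null(n_in_cutoff) || is.na(n_in_cutoff))
    stop("n_in_cutoff (<N_v>) is required for the BM summation correction")
  stopifnot(gamma_s > 0, n_in_cutoff >= 0, cutoff_RC > 0)
  kc <- phys_constants()$coulomb_factor
  crf <- reaction_field_constant(eps_rf)
  pop <- 0
  if (include_sphere_term)
    pop <- pop + 3 * crf * n_in_cutoff / (4 * pi * cutoff_RC^3)
  if (include_box_term)
    pop <- pop + (1 - crf) * n_water / box_edge_L^3
  -(2 * pi / 3) * kc * guest_net_charge * gamma_s * pop
}

#' Average water count within the cutoff sphere
#'
#' Mean number of water oxygens within \code{R_C} of the rule-selected
#' centre (buckyball centre of mass for in-host charging; the guest
#' charge-bearing atom for in-water charging), counted with the minimum
#' image convention.
#'
#' @param frames list of frames; each frame is a matrix of water-oxygen
#'   coordinates (n x 3, nm) or a list with elements \code{waters} (the
#'   oxygen matrix) and optionally \code{solute} (a
#'   \code{solute_structure})
#' @param center_rule "buckyball-COM" or "guest-charge-center"; ignored if
#'   \code{center} is given
#' @param R_C cutoff radius, nm
#' @param L box edge, nm
#' @param center optional explicit centre (3-vector, nm)
#' @return mean count (numeric)
#' @export
estimate_n_in_cutoff <- function(frames,
                                 center_rule = c("buckyball-COM",
                                                 "guest-charge-center"),
                                 R_C, L, center = NULL) {
  center_rule <- match.arg(center_rule)
  if (!length(frames)) stop("no frames supplied")
  counts <- vapply(frames, function(fr) {
    if (is.matrix(fr)) {
      wat <- fr
      ctr <- center
      if (is.null(ctr)) stop("matrix frames need an explicit center")
    } else {
      wat <- fr$waters
      ctr <- center
      if (is.null(ctr)) ctr <- frame_center(fr$solute, center_rule)
    }
    d <- sqrt(rowSums(min_image(sweep(wat, 2, ctr, "-"), L)^2))
    sum(d <= R_C)
  }, numeric(1))
  mean(counts)
}

frame_center <- function(s, center_rule) {
  a <- s$atoms
  if (center_rule == "buckyball-COM") {
    cage <- which(a$group == "host" & a$element == "C" &
                    grepl("^C[0-9]+$", a$name))
    if (length(cage) < 60) cage <- which(a$group == "host")[seq_len(60)]
    colMeans(positions(s)[cage, , drop = FALSE])
  } else {
    gi <- which(a$group == "guest")
    key <- gi[a$name[gi] %in% c("N", "C")][1]
    if (is.na(key)) key <- gi[1]
    positions(s)[key, ]
  }
}
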