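#' Effective pairwise electrostatic interaction function
#'
#' Evaluates the scheme-dependent pair potential factor psi (in 1/nm) such
#' that the interaction energy of charges q_i, q_j separated by \code{rvec}
#' is \code{coulomb_factor * q_i * q_j * psi}.
#' \itemize{
#'   \item CB: plain Coulomb, 1/r.
#'   \item BM: Barker-Watts reaction field with molecule-based cutoff,
#'     1/r + C_RF r^2 / (2 R_C^3) - (1 + C_RF/2) / R_C inside the cutoff
#'     (evaluated on the minimum-image distance), exactly 0 at and beyond
#'     R_C.
#'   \item LS: the periodic Coulomb Green's function of the cubic lattice
#'     with neutralizing background (tinfoil boundary), evaluated by Ewald
#'     summation; no self term is ever included.
#' }
#'
#' @param kind "CB", "BM" or "LS"
#' @param rvec 3-vector or n-by-3 matrix of displacement vectors, nm
#' @param spec a \code{scheme_spec} supplying L, R_C, eps_RF and the Ewald
#'   parameters
#' @return numeric vector of potential factors, 1/nm
#' @export
#' @examples
#' psi("CB", c(1, 0, 0))  # 1
psi <- function(kind = c("CB", "BM", "LS"), rvec, spec = NULL) {
  kind <- match.arg(kind)
  rvec <- rbind_vec(rvec)
  r <- sqrt(rowSums(rvec^2))
  if (any(r <= 0)) stop("singular input: zero separation")
  switch(kind,
    CB = 1 / r,
    BM = {
      rc <- spec$cutoff_RC
      rm <- sqrt(rowSums(min_image(rvec, spec$box_edge_L)^2))
      crf <- reaction_field_constant(spec$eps_reaction_field)
      ifelse(rm < rc,
             1 / rm + crf * rm^2 / (2 * rc^3) - (1 + crf / 2) / rc,
             0)
    },
    LS = ewald_psi(rvec, spec)
  )
}

#' Effective pair function minus its Coulomb component
#'
#' Evaluates \code{psi_eff(r) - 1/r} with the short-range singularity
#' cancelled analytically, so the result stays finite as r approaches 0.
#' This is the kernel through which covalently excluded atom pairs
#' interact in an effective electrostatics scheme.
#'
#' @inheritParams psi
#' @return numeric vector, 1/nm
#' @export
psi_minus_coulomb <- function(kind = c("CB", "BM", "LS"), rvec, spec = NULL) {
  kind <- match.arg(kind)
  rvec <- rbind_vec(rvec)
  r <- sqrt(rowSums(rvec^2))
  switch(kind,
    CB = rep(0, length(r)),
    BM = {
      rc <- spec$cutoff_RC
      rm <- sqrt(rowSums(min_image(rvec, spec$box_edge_L)^2))
      crf <- reaction_field_constant(spec$eps_reaction_field)
      ifelse(rm < rc,
             crf * rm^2 / (2 * rc^3) - (1 + crf / 2) / rc,
             0) + ifelse(abs(rm - r) > 1e-12, 1 / rm - 1 / r, 0)
    },
    LS = ewald_psi(rvec, spec, subtract_central = TRUE)
  )
}

rbind_vec <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3, byrow = TRUE) else as.matrix(x)
}

ewald_params <- function(spec) {
  L <- spec$box_edge_L
  alpha <- spec$ewald_alpha_factor / L
  nmax <- ceiling(6 / (alpha * L))
  g <- expand.grid(x = -nmax:nmax, y = -nmax:nmax, z = -nmax:nmax)
  shifts <- as.matrix(g) * L
  kg <- expand.grid(x = -8:8, y = -8:8, z = -8:8)
  n2 <- rowSums(kg^2)
  kg <- as.matrix(kg[n2 > 0 & n2 <= spec$ewald_kmax, ])
  kvec <- 2 * pi * kg / L
  k2 <- rowSums(kvec^2)
  list(alpha = alpha, shifts = shifts,
       kvec = kvec, kcoef = 4 * pi / L^3 * exp(-k2 / (4 * alpha^2)) / k2,
       const = -pi / (alpha^2 * L^3))
}

# Ewald evaluation of the periodic Coulomb Green's function at displacement
# vectors rvec (n x 3).  With subtract_central, the 1/r of the central image
# is removed analytically (-erf(alpha r)/r instead of erfc(alpha r)/r).
ewald_psi <- function(rvec, spec, subtract_central = FALSE) {
  ep <- ewald_params(spec)
  n <- nrow(rvec)
  out <- rep(ep$const, n)
  for (m in seq_len(nrow(ep$shifts))) {
    sh <- ep$shifts[m, ]
    central <- all(sh == 0)
    d <- sqrt(rowSums(sweep(rvec, 2, sh, "+")^2))
    if (central && subtract_central) {
      out <- out - erf_(ep$alpha * d) / d
    } else {
      out <- out + erfc_(ep$alpha * d) / d
    }
  }
  out + as.vector(cos(rvec %*% t(ep$kvec)) %*% ep$kcoef)
}

erfc_ <- function(x) 2 * stats::pnorm(-sqrt(2) * x)
erf_ <- function(x) 1 - erfc_(x)

#' Guest-environment electrostatic interaction energy
#'
#' Sum over guest atoms i and environment atoms j of
#' \code{coulomb_factor * (lambda q_i) * q_j * psi(kind, r_ij)}.  Guest-guest
#' (intramolecular) pairs are excluded entirely.
#'
#' @param s a tagged \code{solute_structure}
#' @param lambda guest charge-scaling parameter in [0, 1]
#' @param kind electrostatics scheme for the pair function ("CB","BM","LS")
#' @param spec \code{scheme_spec}
#' @param partition "host" (guest-host pairs only) or "all-nonguest"
#' @return energy in kJ/mol
#' @export
guest_env_energy <- function(s, lambda, kind, spec = NULL,
                             partition = c("host", "all-nonguest")) {
  partition <- match.arg(partition)
  stopifnot(lambda >= 0, lambda <= 1)
  kc <- phys_constants()$coulomb_factor
  a <- s$atoms
  gi <- which(a$group == "guest")
  ej <- if (partition == "host") which(a$group == "host")
        else which(a$group != "guest")
  if (!length(gi) || !length(ej) || lambda == 0) return(0)
  pos <- positions(s)
  tot <- 0
  for (i in gi) {
    rij <- sweep(pos[ej, , drop = FALSE], 2, pos[i, ], "-")
    r <- sqrt(rowSums(rij^2))
    if (any(r < 1e-6)) stop("singular input: overlapping atoms")
    tot <- tot + sum(kc * lambda * a$charge[i] * a$charge[ej] *
                       psi(kind, rij, spec))
  }
  tot
}

#' Guest-host direct-interaction correction
#'
#' Replaces the effective-scheme (LS or BM, periodic) guest-host direct
#' electrostatic interaction contained in a raw in-host charging free energy
#' by the Coulombic, nonperiodic one:
#' \code{dG_hs = dG_GH(CB, NPBC) - dG_GH(eff, PBC)}, each term a trapezoidal
#' thermodynamic integration of per-lambda ensemble averages of the
#' guest-host energy derivative.  Since the guest charges scale linearly
#' with lambda, a single rigid configuration reduces this to the
#' full-charge energy difference \code{U_CB(1) - U_eff(1)}.
#'
#' @param x either a \code{lambda_series} whose \code{configs} hold
#'   per-lambda lists of \code{solute_structure} snapshots, or a single
#'   \code{solute_structure} (rigid-complex shortcut)
#' @param kind_eff effective scheme used in the simulation, "LS" or "BM"
#' @param spec \code{scheme_spec} of the simulation box
#' @param lambdas lambda grid used when \code{x} is a single structure
#' @return correction in kJ/mol (0 for an uncharged host)
#' @export
dG_hs <- function(x, kind_eff = c("LS", "BM"), spec,
                  lambdas = seq(0, 1, 0.1)) {
  kind_eff <- match.arg(kind_eff)
  if (inherits(x, "solute_structure")) {
    cfgs <- rep(list(list(x)), length(lambdas))
  } else if (inherits(x, "lambda_series")) {
    if (is.null(x$configs)) stop("lambda series carries no configurations")
    cfgs <- x$configs
    lambdas <- x$lambdas
  } else stop("x must be a solute_structure or a lambda_series with configs")
  dudl <- function(kind) vapply(cfgs, function(cfg)
    mean(vapply(cfg, function(s)
      guest_env_energy(s, 1, kind, spec, "host"), numeric(1))), numeric(1))
  ti <- function(kind) sum(trapezoid_weights(lambdas) * dudl(kind))
  ti("CB") - ti(kind_eff)
}

#' Excluded-pair interaction correction
#'
#' Removes the methodology-dependent electrostatic interaction between
#' covalently excluded guest atom pairs (first and second neighbours).
#' Excluded pairs interact through the effective scheme reduced by its
#' Coulombic component and exempt of the self term, i.e. through the
#' kernel \code{(psi_eff - 1/r) - lim_(r->0)(psi_eff - 1/r)}: for the LS
#' scheme the distance-dependent remainder of the periodic Green's
#' function (curvature of order r^2/L^3), for the BM scheme the
#' reaction-field curvature \code{C_RF r^2 / (2 R_C^3)}.  Since both
#' charges of a pair scale with lambda the thermodynamic integral is
#' analytic and the correction is minus the full-charge excluded-pair
#' energy evaluated with that kernel.
#'
#' @param s a \code{solute_structure} with a complete guest exclusion list
#' @param kind_eff "LS" or "BM"
#' @param spec \code{scheme_spec}
#' @return correction in kJ/mol (0 for empty exclusion lists or monoatomic
#'   guests)
#' @export
dG_excl <- function(s, kind_eff = c("LS", "BM"), spec) {
  kind_eff <- match.arg(kind_eff)
  ex <- s$exclusions
  if (!nrow(ex)) return(0)
  kc <- phys_constants()$coulomb_factor
  pos <- positions(s)
  q <- s$atoms$charge
  rij <- pos[ex[, 2], , drop = FALSE] - pos[ex[, 1], , drop = FALSE]
  kern <- psi_minus_coulomb(kind_eff, rij, spec) -
    psi_self_constant(kind_eff, spec)
  -sum(kc * q[ex[, 1]] * q[ex[, 2]] * kern)
}

# zero-separation limit of psi_eff - 1/r (the per-pair self constant)
psi_self_constant <- function(kind, spec) {
  switch(kind,
    CB = 0,
    BM = {
      crf <- reaction_field_constant(spec$eps_reaction_field)
      -(1 + crf / 2) / spec$cutoff_RC
    },
    LS = ewald_minus_coulomb(matrix(0, 1, 3), spec)
  )
}
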