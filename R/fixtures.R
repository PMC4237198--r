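#' Recipe for a synthetic buckyball guest-host fixture
#'
#' The benchmark systems are an artificial C60 cage (all C-C bonds extended
#' to 0.2 nm), bare (CAPO) or functionalized with a formamide (CHB),
#' methylammonium (CPOS) or formate (CNEG) group, optionally holding a
#' methylammonium (MAM, +1 e) or acetate (ACE, -1 e) guest.
#'
#' @param host one of "CAPO", "CHB", "CPOS", "CNEG"
#' @param guest one of "MAM", "ACE", "none"
#' @param bond_length C-C bond length of the cage, nm
#' @param seed integer seed for any stochastic placement
#' @param jitter_sigma standard deviation of the random rigid-body
#'   displacement applied to the guest, nm (0 = exactly centred)
#' @return object of class \code{fixture_recipe}
#' @export
fixture_recipe <- function(host = c("CAPO", "CHB", "CPOS", "CNEG"),
                           guest = c("none", "MAM", "ACE"),
                           bond_length = 0.2, seed = 1L, jitter_sigma = 0) {
  host <- match.arg(host); guest <- match.arg(guest)
  stopifnot(bond_length > 0, jitter_sigma >= 0)
  structure(list(host = host, guest = guest, bond_length = bond_length,
                 seed = as.integer(seed), jitter_sigma = jitter_sigma),
            class = "fixture_recipe")
}

# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Truncated-icosahedron vertex set with unit edge length, centred at origin.
trunc_icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  base <- rbind(c(0, 1, 3 * phi),
                c(1, 2 + phi, 2 * phi),
                c(phi, 2, 2 * phi + 1))
  v <- list()
  for (i in 1:3) {
    b <- base[i, ]
    for (cyc in list(b, b[c(2, 3, 1)], b[c(3, 1, 2)]))
      for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) for (s3 in c(-1, 1))
        v[[length(v) + 1L]] <- cyc * c(s1, s2, s3)
  }
  v <- unique(do.call(rbind, v))
  v / 2  # edge length of this construction is 2
}

# default stand-in partial charge sets (NOT force-field values); each group
# sums exactly to its nominal net charge
fixture_charge_sets <- function() {
  list(
    MAM  = c(N = -0.6, H1 = 0.4, H2 = 0.4, H3 = 0.4, CH3 = 0.4),       # +1
    ACE  = c(CH3 = 0.0, C = 0.27, O1 = -0.635, O2 = -0.635),           # -1
    CHB  = c(C = 0.45, O = -0.45, N = -0.72, H1 = 0.36, H2 = 0.36),    #  0
    CPOS = c(CH2 = 0.4, N = -0.6, H1 = 0.4, H2 = 0.4, H3 = 0.4),       # +1
    CNEG = c(C = 0.27, O1 = -0.635, O2 = -0.635)                       # -1
  )
}

atom_row <- function(name, element, pos, charge, polar = FALSE,
                     group = "host") {
  data.frame(name = name, element = element,
             x = pos[1], y = pos[2], z = pos[3],
             charge = charge, radius = NA_real_,
             is_polar_hydrogen = polar, group = group,
             stringsAsFactors = FALSE)
}

# guest geometry around its charge-bearing centre at the origin
build_guest_atoms <- function(guest) {
  q <- fixture_charge_sets()[[guest]]
  tet <- 109.47 * pi / 180
  if (guest == "MAM") {
    # N at origin, united CH3 along +x, three ammonium hydrogens tetrahedral
    hdir <- function(az) c(cos(pi - tet),
                           sin(pi - tet) * cos(az), sin(pi - tet) * sin(az))
    rbind(
      atom_row("N", "N", c(0, 0, 0), q[["N"]], group = "guest"),
      atom_row("H1", "H", 0.10 * hdir(0), q[["H1"]], TRUE, "guest"),
      atom_row("H2", "H", 0.10 * hdir(2 * pi / 3), q[["H2"]], TRUE, "guest"),
      atom_row("H3", "H", 0.10 * hdir(4 * pi / 3), q[["H3"]], TRUE, "guest"),
      atom_row("CH3", "CH3", c(0.147, 0, 0), q[["CH3"]], group = "guest"))
  } else if (guest == "ACE") {
    # carboxylate C at origin, united CH3 along +x, two O splayed at 123 deg
    odir <- function(sgn) c(cos(123 * pi / 180), sgn * sin(123 * pi / 180), 0)
    rbind(
      atom_row("C", "C", c(0, 0, 0), q[["C"]], group = "guest"),
      atom_row("CH3", "CH3", c(0.153, 0, 0), q[["CH3"]], group = "guest"),
      atom_row("O1", "OM", 0.125 * odir(1), q[["O1"]], group = "guest"),
      atom_row("O2", "OM", 0.125 * odir(-1), q[["O2"]], group = "guest"))
  } else stop("unknown guest label: ", guest)
}

guest_bonds <- function(guest) {
  if (guest == "MAM") rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5))
  else rbind(c(1, 2), c(1, 3), c(1, 4))
}

#' Build a (possibly functionalized) buckyball host cage
#'
#' Places 60 carbon atoms on a truncated-icosahedron hull scaled so that all
#' 90 bonded C-C distances equal \code{recipe$bond_length}, all carbons
#' uncharged.  For CHB, CPOS and CNEG a small functional group (net charge
#' 0, +1, -1) is bonded covalently to one cage atom, pointing outward.
#'
#' @param recipe a \code{fixture_recipe}
#' @return a \code{solute_structure} with all atoms tagged "host"
#' @export
#' @examples
#' cage <- build_buckyball(fixture_recipe(host = "CAPO"))
#' nrow(cage$atoms)  # 60
build_buckyball <- function(recipe) {
  stopifnot(inherits(recipe, "fixture_recipe"))
  v <- trunc_icosahedron() * recipe$bond_length
  atoms <- do.call(rbind, lapply(seq_len(nrow(v)), function(i)
    atom_row(paste0("C", i), "C", v[i, ], 0, group = "host")))
  d <- as.matrix(dist(v))
  bonds <- which(upper.tri(d) & abs(d - recipe$bond_length) < 1e-9,
                 arr.ind = TRUE)
  bonds <- cbind(bonds[, 1], bonds[, 2])
  label <- recipe$host
  if (recipe$host != "CAPO") {
    q <- fixture_charge_sets()[[recipe$host]]
    anchor <- 1L
    u <- v[anchor, ] / sqrt(sum(v[anchor, ]^2))  # outward radial direction
    # two unit vectors perpendicular to u
    p1 <- c(-u[2], u[1], 0); if (sum(p1^2) < 1e-12) p1 <- c(1, 0, 0)
    p1 <- p1 / sqrt(sum(p1^2)); p2 <- c(u[2] * p1[3] - u[3] * p1[2],
                                        u[3] * p1[1] - u[1] * p1[3],
                                        u[1] * p1[2] - u[2] * p1[1])
    base <- v[anchor, ]
    grp <- switch(recipe$host,
      CHB = rbind(  # formamide -C(=O)NH2
        atom_row("CG", "C", base + 0.15 * u, q[["C"]]),
        atom_row("OG", "O", base + 0.15 * u + 0.123 * p1, q[["O"]]),
        atom_row("NG", "N", base + 0.28 * u, q[["N"]]),
        atom_row("HG1", "H", base + 0.28 * u + 0.10 * p1, q[["H1"]], TRUE),
        atom_row("HG2", "H", base + 0.38 * u, q[["H2"]], TRUE)),
      CPOS = rbind( # -CH2-NH3+
        atom_row("CG", "CH2", base + 0.15 * u, q[["CH2"]]),
        atom_row("NG", "N", base + 0.297 * u, q[["N"]]),
        atom_row("HG1", "H", base + 0.297 * u + 0.10 * p1, q[["H1"]], TRUE),
        atom_row("HG2", "H", base + 0.297 * u + 0.10 * (-0.5 * p1 + 0.866 * p2),
                 q[["H2"]], TRUE),
        atom_row("HG3", "H", base + 0.297 * u + 0.10 * (-0.5 * p1 - 0.866 * p2),
                 q[["H3"]], TRUE)),
      CNEG = rbind( # formate -COO-
        atom_row("CG", "C", base + 0.15 * u, q[["C"]]),
        atom_row("OG1", "OM", base + 0.15 * u + 0.125 * p1, q[["O1"]]),
        atom_row("OG2", "OM", base + 0.15 * u - 0.125 * p1, q[["O2"]])))
    n0 <- nrow(atoms)
    gb <- switch(recipe$host,
      CHB  = rbind(c(anchor, n0 + 1), c(n0 + 1, n0 + 2), c(n0 + 1, n0 + 3),
                   c(n0 + 3, n0 + 4), c(n0 + 3, n0 + 5)),
      CPOS = rbind(c(anchor, n0 + 1), c(n0 + 1, n0 + 2), c(n0 + 2, n0 + 3),
                   c(n0 + 2, n0 + 4), c(n0 + 2, n0 + 5)),
      CNEG = rbind(c(anchor, n0 + 1), c(n0 + 1, n0 + 2), c(n0 + 1, n0 + 3)))
    atoms <- rbind(atoms, grp)
    bonds <- rbind(bonds, gb)
  }
  solute_structure(atoms, bonds, label = label)
}

#' Build a guest-host complex fixture
#'
#' The guest is placed with its charge-bearing centre (MAM nitrogen or ACE
#' carboxylate carbon) at the centre of mass of the 60 cage carbons, with an
#' optional random rigid-body displacement of standard deviation
#' \code{jitter_sigma}.  Placement is rejected (and retried, then aborted)
#' if any guest-host atom pair comes closer than 0.12 nm.
#'
#' @param recipe a \code{fixture_recipe} with \code{guest != "none"}
#' @return a \code{solute_structure} tagged guest/host, guest exclusions
#'   (1-2 and 1-3 neighbours) complete
#' @export
#' @examples
#' cplx <- build_complex(fixture_recipe(host = "CNEG", guest = "MAM"))
#' net_charge(cplx)  # 0
build_complex <- function(recipe) {
  stopifnot(inherits(recipe, "fixture_recipe"))
  if (recipe$guest == "none") stop("recipe$guest must be MAM or ACE")
  host <- build_buckyball(recipe)
  guest_atoms <- build_guest_atoms(recipe$guest)
  gb <- guest_bonds(recipe$guest)
  ng <- nrow(guest_atoms)
  cage_com <- colMeans(positions(host)[seq_len(60), ])
  place <- function(shift) {
    ga <- guest_atoms
    ga[, c("x", "y", "z")] <- sweep(as.matrix(ga[, c("x", "y", "z")]), 2,
                                    cage_com + shift, "+")
    ga
  }
  ok <- function(ga) {
    dg <- as.matrix(ga[, c("x", "y", "z")]); dh <- positions(host)
    dmin <- min(sqrt(outer(rowSums(dg^2), rowSums(dh^2), "+") -
                       2 * dg %*% t(dh)))
    dmin >= 0.12
  }
  ga <- with_seed(recipe$seed, {
    placed <- NULL
    for (try in 1:100) {
      shift <- if (recipe$jitter_sigma > 0)
        stats::rnorm(3, 0, recipe$jitter_sigma) else c(0, 0, 0)
      cand <- place(shift)
      if (ok(cand)) { placed <- cand; break }
      if (recipe$jitter_sigma == 0) break
    }
    if (is.null(placed))
      stop("steric placement impossible: guest-host contact below 0.12 nm")
    placed
  })
  atoms <- rbind(ga, host$atoms)
  bonds <- rbind(gb, host$bonds + ng)
  # exclusions: guest 1-2/1-3 pairs (guest atoms come first)
  excl <- exclusions_from_bonds(gb, ng)
  solute_structure(atoms, bonds, exclusions = excl,
                   label = paste0("complex:", recipe$guest, "-", recipe$host))
}

#' Synthetic per-lambda derivative series
#'
#' Builds an 11-point lambda series whose values follow a quadratic profile
#' in lambda.  The profile is shifted so that its trapezoidal integral on
#' the grid equals \code{target_dG} exactly before noise; Gaussian noise of
#' standard deviation \code{noise_sigma} is then added independently per
#' point.
#'
#' @param target_dG desired trapezoidal integral, kJ/mol
#' @param curvature coefficient of the (lambda - 1/2)^2 term, kJ/mol
#' @param noise_sigma per-point Gaussian noise, kJ/mol
#' @param seed integer seed for the noise draws
#' @param lambdas lambda grid (default the 11 standard charge states)
#' @return a \code{lambda_series}
#' @export
synth_lambda_series <- function(target_dG, curvature = 0, noise_sigma = 0,
                                seed = 1L, lambdas = seq(0, 1, 0.1)) {
  stopifnot(noise_sigma >= 0)
  quad <- curvature * (lambdas - 0.5)^2
  w <- trapezoid_weights(lambdas)
  offset <- (target_dG - sum(w * quad)) / sum(w)
  values <- quad + offset
  if (noise_sigma > 0)
    values <- values + with_seed(seed, stats::rnorm(length(values), 0,
                                                    noise_sigma))
  lambda_series(lambdas, values,
                errors = rep(noise_sigma, length(lambdas)))
}
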