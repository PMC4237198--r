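#' Dielectric grid for continuum-electrostatics solves
#'
#' Discretizes a cubic domain of edge \code{L} into \code{n^3} nodes (node
#' spacing \code{h = L/n}), assigns each node a relative permittivity (1
#' inside the solute van der Waals envelope, \code{eps_solvent} outside) and
#' spreads the atomic partial charges onto the nodes with trilinear
#' (cloud-in-cell) assignment.  The solute is translated so that its centre
#' of mass sits at the domain centre.
#'
#' @param s a \code{solute_structure} with radii assigned (see
#'   \code{\link{assign_radii}})
#' @param L domain edge length, nm
#' @param spacing target grid spacing, nm (adjusted so that it divides L)
#' @param eps_solvent relative permittivity outside the solute envelope
#' @param boundary "PBC" or "NPBC"
#' @param charges optional per-atom charge vector overriding
#'   \code{s$atoms$charge} (used for lambda scaling)
#' @return object of class \code{dielectric_grid}
#' @export
dielectric_grid <- function(s, L, spacing = 0.05, eps_solvent = 1,
                            boundary = c("PBC", "NPBC"), charges = NULL) {
  boundary <- match.arg(boundary)
  n <- max(8L, as.integer(round(L / spacing)))
  h <- L / n
  pos <- positions(s)
  shift <- rep(L / 2, 3) - colMeans(pos)
  pos <- sweep(pos, 2, shift, "+")
  if (is.null(charges)) charges <- s$atoms$charge
  stopifnot(length(charges) == nrow(pos))
  # node coordinates (i-1)*h, i = 1..n
  rad <- s$atoms$radius
  if (any(!is.finite(rad))) stop("structure has unassigned radii")
  ax <- (seq_len(n) - 1) * h
  inside <- function(ox, oy, oz)
    mark_inside(pos, rad, ax + ox, ax + oy, ax + oz, L, boundary)
  eps <- array(eps_solvent, dim = c(n, n, n))
  eps[inside(0, 0, 0)] <- 1
  # face permittivities from the fraction of each edge lying inside the
  # solute envelope (3-point sampling), combined harmonically so that the
  # normal flux is continuous across the dielectric boundary
  frac_face <- function(axis) {
    f <- array(0, dim = c(n, n, n))
    for (t in c(1, 3, 5) / 6) {
      o <- c(0, 0, 0); o[axis] <- t * h
      f <- f + inside(o[1], o[2], o[3])
    }
    f / 3
  }
  face_of <- function(f) 1 / (f + (1 - f) / eps_solvent)
  feps <- list(fx = face_of(frac_face(1)), fy = face_of(frac_face(2)),
               fz = face_of(frac_face(3)))
  q <- array(0, dim = c(n, n, n))
  for (i in seq_len(nrow(pos))) {
    if (charges[i] == 0) next
    w <- cic_weights(pos[i, ], h, n)
    q[w$idx] <- q[w$idx] + charges[i] * w$w
  }
  structure(list(n = n, h = h, L = L, eps = eps, feps = feps, q = q,
                 pos = pos, charges = charges, eps_solvent = eps_solvent,
                 boundary = boundary, shift = shift),
            class = "dielectric_grid")
}

wrapdiff <- function(x, x0, L, boundary) {
  d <- x - x0
  if (boundary == "PBC") d - L * round(d / L) else d
}

# logical array: is grid point (gx[i], gy[j], gz[k]) inside any atom sphere
mark_inside <- function(pos, rad, gx, gy, gz, L, boundary) {
  out <- array(FALSE, dim = c(length(gx), length(gy), length(gz)))
  for (i in which(rad > 0)) {
    rr <- rad[i]
    dx <- wrapdiff(gx, pos[i, 1], L, boundary)
    dy <- wrapdiff(gy, pos[i, 2], L, boundary)
    dz <- wrapdiff(gz, pos[i, 3], L, boundary)
    ix <- which(abs(dx) <= rr); iy <- which(abs(dy) <= rr)
    iz <- which(abs(dz) <= rr)
    if (!length(ix) || !length(iy) || !length(iz)) next
    d2 <- outer(outer(dx[ix]^2, dy[iy]^2, "+"), dz[iz]^2, "+")
    sub <- out[ix, iy, iz]
    sub[d2 <= rr^2] <- TRUE
    out[ix, iy, iz] <- sub
  }
  out
}

# trilinear assignment/interpolation stencil for one point
cic_weights <- function(p, h, n) {
  f <- p / h               # node index space (node i at (i-1)h)
  i0 <- floor(f)
  t <- f - i0
  ids <- lapply(1:3, function(d) ((c(i0[d], i0[d] + 1)) %% n) + 1L)
  wts <- lapply(1:3, function(d) c(1 - t[d], t[d]))
  idx <- as.matrix(expand.grid(ids[[1]], ids[[2]], ids[[3]]))
  w <- as.vector(outer(outer(wts[[1]], wts[[2]]), wts[[3]]))
  list(idx = idx, w = w)
}

shift_arr <- function(a, axis, by) {
  n <- dim(a)[axis]
  idx <- ((seq_len(n) - 1 + by) %% n) + 1L
  switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# face permittivities, fx[i,j,k] between node i and i+1 etc.; taken from
# the edge-fraction assignment stored on the grid, with a plain harmonic
# mean of node values as fallback
face_eps <- function(grid) {
  if (!is.null(grid$feps)) return(grid$feps)
  eps <- grid$eps
  hm <- function(a, b) 2 * a * b / (a + b)
  list(fx = hm(eps, shift_arr(eps, 1, 1)),
       fy = hm(eps, shift_arr(eps, 2, 1)),
       fz = hm(eps, shift_arr(eps, 3, 1)))
}

#' Finite-difference Poisson solver on a dielectric grid
#'
#' Solves the discrete heterogeneous-dielectric Poisson equation
#' div(eps grad phi) = -rho/eps0 with a symmetric 7-point stencil and
#' preconditioned conjugate gradients (Jacobi preconditioner).  Under PBC a
#' uniform neutralizing background is implied and the solution is gauged to
#' zero mean over the box; under NPBC the boundary nodes are held at the
#' analytic solvent-screened Coulomb potential of the charge set.
#'
#' @param grid a \code{dielectric_grid}
#' @param tol_energy convergence threshold on the change of the grid
#'   electrostatic free energy between successive checks, kJ/mol
#' @param maxit iteration cap (error if exceeded)
#' @return potential array, kJ mol^-1 e^-1 per node, with attribute
#'   \code{iterations}
#' @export
solve_poisson_fd <- function(grid, tol_energy = 0.01, maxit = 20000L) {
  kc <- phys_constants()$coulomb_factor
  n <- grid$n; h <- grid$h
  fe <- face_eps(grid)
  fxm <- shift_arr(fe$fx, 1, -1); fym <- shift_arr(fe$fy, 2, -1)
  fzm <- shift_arr(fe$fz, 3, -1)
  diag_ <- fe$fx + fxm + fe$fy + fym + fe$fz + fzm
  amul <- function(phi)
    diag_ * phi -
      fe$fx * shift_arr(phi, 1, 1) - fxm * shift_arr(phi, 1, -1) -
      fe$fy * shift_arr(phi, 2, 1) - fym * shift_arr(phi, 2, -1) -
      fe$fz * shift_arr(phi, 3, 1) - fzm * shift_arr(phi, 3, -1)
  b <- 4 * pi * kc * grid$q / h
  pbc <- grid$boundary == "PBC"
  interior <- NULL
  phi <- array(0, dim = dim(b))
  if (pbc) {
    b <- b - mean(b)   # neutralizing background
  } else {
    bmask <- array(FALSE, dim = dim(b))
    bmask[c(1, n), , ] <- TRUE; bmask[, c(1, n), ] <- TRUE
    bmask[, , c(1, n)] <- TRUE
    interior <- !bmask
    phi[bmask] <- boundary_potential(grid)[bmask]
    b <- b - amul(phi)        # fold Dirichlet values into the RHS
    b[bmask] <- 0
  }
  # PCG on the (interior) system
  x <- array(0, dim = dim(b))
  r <- b
  z <- r / diag_
  if (pbc) z <- z - mean(z) else z[!interior] <- 0
  p <- z
  rz <- sum(r * z)
  b2 <- sqrt(sum(b^2))
  if (b2 == 0) return(structure(phi, iterations = 0L))
  e_prev <- Inf; it <- 0L
  repeat {
    it <- it + 1L
    if (it > maxit) stop("FD Poisson solver did not converge in ", maxit,
                         " iterations")
    ap <- amul(p)
    if (!pbc) ap[!interior] <- 0
    alpha <- rz / sum(p * ap)
    x <- x + alpha * p
    r <- r - alpha * ap
    if (it %% 20 == 0 || sqrt(sum(r^2)) < 1e-10 * b2) {
      e_now <- 0.5 * sum(grid$q * (phi + x))
      if (abs(e_now - e_prev) < tol_energy &&
          sqrt(sum(r^2)) < 1e-5 * b2) break
      if (sqrt(sum(r^2)) < 1e-10 * b2) break
      e_prev <- e_now
    }
    z <- r / diag_
    if (pbc) z <- z - mean(z) else z[!interior] <- 0
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  phi <- phi + x
  if (pbc) phi <- phi - mean(phi)
  structure(phi, iterations = it)
}

# analytic Dirichlet boundary values: solvent-screened Coulomb potential
boundary_potential <- function(grid) {
  kc <- phys_constants()$coulomb_factor
  n <- grid$n; h <- grid$h
  ax <- (seq_len(n) - 1) * h
  phi <- array(0, dim = c(n, n, n))
  idx <- which(
    slice.index(phi, 1) %in% c(1L, n) |
    slice.index(phi, 2) %in% c(1L, n) |
    slice.index(phi, 3) %in% c(1L, n))
  coords <- arrayInd(idx, dim(phi))
  pts <- (coords - 1) * h
  val <- numeric(length(idx))
  for (i in seq_len(nrow(grid$pos))) {
    if (grid$charges[i] == 0) next
    d <- sqrt(rowSums(sweep(pts, 2, grid$pos[i, ], "-")^2))
    val <- val + kc * grid$charges[i] / (grid$eps_solvent * pmax(d, h))
  }
  phi[idx] <- val
  phi
}

#' Interpolate a grid potential at atom sites
#'
#' Trilinear interpolation, consistent with the cloud-in-cell charge
#' assignment used to build the grid.
#'
#' @param grid the \code{dielectric_grid} the potential was solved on
#' @param phi potential array from a solver
#' @param which_atoms atom indices (default all)
#' @return numeric vector of potentials, kJ mol^-1 e^-1
#' @export
potential_at_sites <- function(grid, phi, which_atoms = NULL) {
  if (is.null(which_atoms)) which_atoms <- seq_len(nrow(grid$pos))
  vapply(which_atoms, function(i) {
    w <- cic_weights(grid$pos[i, ], grid$h, grid$n)
    sum(phi[w$idx] * w$w)
  }, numeric(1))
}

# --- FFT Green's-function solver ------------------------------------------

# Fourier-space pairwise interaction kernel on the grid (kJ/mol/e^2 per
# cell pair).  The periodic Coulomb (LS) kernel is defined spectrally as
# 4 pi k_C / k^2 (zero mean mode), which is positive semidefinite; the BM
# and CB kernels are expressed as LS plus the FFT of their bounded,
# smooth real-space difference from the periodic Coulomb function, so
# that the resulting operators remain sign-definite for the bound-charge
# solve.  The cell self-interaction implied by this construction cancels
# in the full-minus-reference free-energy evaluation (no self term
# survives).
fft_kernel_hat <- function(grid, kernel = c("LS", "BM", "CB"), spec) {
  kernel <- match.arg(kernel)
  key <- paste(kernel, grid$n, signif(grid$L, 10),
               if (kernel == "BM") paste(spec$cutoff_RC,
                                         spec$eps_reaction_field) else "",
               spec$ewald_alpha_factor, spec$ewald_kmax)
  cached <- .kernel_cache[[key]]
  if (!is.null(cached)) return(cached)
  kc <- phys_constants()$coulomb_factor
  n <- grid$n; h <- grid$h; L <- grid$L
  # eigenvalues of the 7-point discrete Laplacian: the LS kernel is its
  # exact inverse, so the homogeneous FFT solve reproduces the FD solver
  # and short-range discretization errors are shared between kernels
  freq <- 2 * pi / L * c(0:(n %/% 2), -((n - (n %/% 2 + 1)):1))
  s2 <- (4 / h^2) * sin(freq * h / 2)^2
  k2 <- outer(outer(s2, s2, "+"), s2, "+")
  Ghat <- array(0, dim = c(n, n, n))
  Ghat[k2 > 0] <- 4 * pi * kc / (k2[k2 > 0] * h^3)  # discrete pair units
  if (kernel != "LS") {
    lspec <- spec
    lspec$box_edge_L <- L   # Ewald evaluation on this grid's box
    ax <- (seq_len(n) - 1) * h
    axm <- ax - L * round(ax / L)
    g <- as.matrix(expand.grid(x = axm, y = axm, z = axm))
    # bounded difference psi_kernel - psi_LS (finite at zero displacement)
    dls <- ewald_minus_coulomb(g, lspec)
    if (kernel == "BM") {
      rc <- spec$cutoff_RC
      crf <- reaction_field_constant(spec$eps_reaction_field)
      rm <- sqrt(rowSums(g^2))
      dbm <- ifelse(rm < rc, crf * rm^2 / (2 * rc^3) - (1 + crf / 2) / rc,
                    0) - ifelse(rm < rc, 0, 1 / pmax(rm, h / 2))
      dpsi <- dbm - dls
    } else {
      dpsi <- -dls
    }
    Ghat <- Ghat + stats::fft(array(kc * dpsi, dim = c(n, n, n)))
  }
  assign(key, Ghat, envir = .kernel_cache)
  Ghat
}

# psi_LS - 1/r on a displacement matrix, with the zero-displacement entry
# taking the analytic r -> 0 limit (the cubic-lattice self constant / L)
ewald_minus_coulomb <- function(g, spec) {
  r <- sqrt(rowSums(g^2))
  out <- numeric(nrow(g))
  nz <- r > 0
  if (any(nz)) out[nz] <- ewald_psi(g[nz, , drop = FALSE], spec,
                                    subtract_central = TRUE)
  if (any(!nz)) {
    ep <- ewald_params(spec)
    lim <- ep$const - 2 * ep$alpha / sqrt(pi) + sum(ep$kcoef)
    sh <- ep$shifts[rowSums(abs(ep$shifts)) > 0, , drop = FALSE]
    if (nrow(sh)) {
      d <- sqrt(rowSums(sh^2))
      lim <- lim + sum(erfc_(ep$alpha * d) / d)
    }
    out[!nz] <- lim
  }
  out
}

.kernel_cache <- new.env(parent = emptyenv())

conv_fft <- function(Ghat, q) {
  Re(stats::fft(Ghat * stats::fft(q), inverse = TRUE)) / length(q)
}

#' FFT Green's-function Poisson solver
#'
#' Computes the potential generated by the grid charges through an
#' arbitrary pairwise interaction kernel ("LS" periodic Coulomb, "BM"
#' truncated Barker-Watts, "CB" in-box Coulomb) by FFT convolution.  For a
#' heterogeneous permittivity map the dielectric response is obtained by
#' fixed-point iteration on the bound (polarization) charges with
#' under-relaxation.
#'
#' @param grid a \code{dielectric_grid}
#' @param kernel "LS", "BM" or "CB"
#' @param spec \code{scheme_spec} supplying cutoff/Ewald parameters
#' @param tol relative residual tolerance of the bound-charge solve
#' @param maxit iteration cap
#' @return potential array, kJ mol^-1 e^-1, with attribute \code{iterations}
#' @export
solve_poisson_fft <- function(grid, kernel = c("LS", "BM", "CB"), spec,
                              tol = 1e-6, maxit = 500L) {
  kernel <- match.arg(kernel)
  kc <- phys_constants()$coulomb_factor
  Ghat <- fft_kernel_hat(grid, kernel, spec)
  q <- grid$q
  homogeneous <- all(abs(grid$eps - grid$eps[1]) < 1e-12)
  if (homogeneous && abs(grid$eps[1] - 1) < 1e-12) {
    phi <- conv_fft(Ghat, q)
    return(structure(phi, iterations = 1L))
  }
  fe <- face_eps(grid)
  exm <- shift_arr(fe$fx, 1, -1); eym <- shift_arr(fe$fy, 2, -1)
  ezm <- shift_arr(fe$fz, 3, -1)
  # bound (polarization) charge induced by a potential field, e per cell
  bound_charge <- function(phi)
    (grid$h / (4 * pi * kc)) * (
      (fe$fx - 1) * (shift_arr(phi, 1, 1) - phi) +
      (exm - 1) * (shift_arr(phi, 1, -1) - phi) +
      (fe$fy - 1) * (shift_arr(phi, 2, 1) - phi) +
      (eym - 1) * (shift_arr(phi, 2, -1) - phi) +
      (fe$fz - 1) * (shift_arr(phi, 3, 1) - phi) +
      (ezm - 1) * (shift_arr(phi, 3, -1) - phi))
  # self-consistency:  qb = B(G (q + qb))  <=>  (I - BG) qb = B(G q);
  # the operator I - BG has a mostly-real spectrum clustered in [1, eps],
  # solved matrix-free with restarted GMRES
  amul <- function(x) x - bound_charge(conv_fft(Ghat, x))
  rhs <- bound_charge(conv_fft(Ghat, q))
  sol <- gmres(amul, rhs, tol = tol, restart = 30L, maxit = maxit)
  structure(conv_fft(Ghat, q + sol$x), iterations = sol$iterations)
}

# matrix-free restarted GMRES on arrays
gmres <- function(amul, b, tol = 1e-6, restart = 30L, maxit = 500L) {
  nb <- sqrt(sum(b^2))
  x <- array(0, dim = dim(b))
  if (nb == 0) return(list(x = x, iterations = 0L))
  total <- 0L
  repeat {
    r <- b - amul(x)
    beta <- sqrt(sum(r^2))
    if (beta < tol * nb) return(list(x = x, iterations = total))
    V <- vector("list", restart + 1L)
    H <- matrix(0, restart + 1L, restart)
    cs <- sn <- numeric(restart)
    g <- numeric(restart + 1L); g[1] <- beta
    V[[1]] <- r / beta
    k <- 0L
    for (j in seq_len(restart)) {
      total <- total + 1L
      if (total > maxit)
        stop("FFT Poisson solver (GMRES) did not converge in ", maxit,
             " iterations")
      w <- amul(V[[j]])
      for (i in seq_len(j)) {          # modified Gram-Schmidt
        H[i, j] <- sum(w * V[[i]])
        w <- w - H[i, j] * V[[i]]
      }
      H[j + 1L, j] <- sqrt(sum(w^2))
      V[[j + 1L]] <- w / H[j + 1L, j]
      for (i in seq_len(j - 1L)) {     # apply previous Givens rotations
        t1 <- cs[i] * H[i, j] + sn[i] * H[i + 1L, j]
        H[i + 1L, j] <- -sn[i] * H[i, j] + cs[i] * H[i + 1L, j]
        H[i, j] <- t1
      }
      d <- sqrt(H[j, j]^2 + H[j + 1L, j]^2)
      cs[j] <- H[j, j] / d; sn[j] <- H[j + 1L, j] / d
      H[j, j] <- d; H[j + 1L, j] <- 0
      g[j + 1L] <- -sn[j] * g[j]; g[j] <- cs[j] * g[j]
      k <- j
      if (abs(g[j + 1L]) < tol * nb) break
    }
    y <- backsolve(H[seq_len(k), seq_len(k), drop = FALSE], g[seq_len(k)])
    for (i in seq_len(k)) x <- x + y[i] * V[[i]]
    if (abs(g[k + 1L]) < tol * nb) return(list(x = x, iterations = total))
  }
}
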