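test_that("radius assignment follows the envelope rules", {
  cplx <- build_complex(fixture_recipe(host = "CHB", guest = "MAM"))
  s <- assign_radii(cplx)
  a <- s$atoms
  expect_true(all(a$radius[a$is_polar_hydrogen] == 0.05))
  # LJ-minimum distance minus the water probe radius
  s2 <- assign_radii(cplx, lj_table = c(C = 0.34, CH2 = 0.34, CH3 = 0.34,
                                        N = 0.34, O = 0.34, OM = 0.34,
                                        H = 0.34))
  expect_true(all(abs(s2$atoms$radius[!s2$atoms$is_polar_hydrogen] - 0.20)
                  < 1e-12))
  expect_error(assign_radii(cplx, lj_table = c(C = 0.41)), "missing")
  expect_error(assign_radii(cplx, lj_table = c(C = 0.1, CH2 = 0.1,
                                               CH3 = 0.1, N = 0.1,
                                               O = 0.1, OM = 0.1, H = 0.1)),
               "invalid")
})

test_that("FD solver reproduces the Coulomb potential for a vacuum point charge", {
  ion <- make_ion(radius = 0)
  kc <- phys_constants()$coulomb_factor
  g <- dielectric_grid(ion, L = 2.0, spacing = 0.05, eps_solvent = 1,
                       boundary = "NPBC")
  phi <- solve_poisson_fd(g, tol_energy = 1e-4)
  # compare on axis points between 4 h and box/3 from the charge
  centre <- g$pos[1, ]
  n <- g$n; h <- g$h
  i0 <- round(centre[1] / h) + 1
  for (k in 4:13) {
    node_phi <- phi[i0 + k, i0, i0]
    r <- k * h
    expect_equal(node_phi, kc / r, tolerance = 0.02)
  }
})

test_that("zero charge gives the zero potential in the PBC gauge", {
  s <- make_ion(q = 0, radius = 0.2)
  g <- dielectric_grid(s, L = 1.6, spacing = 0.1, eps_solvent = 66.6,
                       boundary = "PBC")
  phi <- solve_poisson_fd(g)
  expect_true(all(phi == 0))
})

test_that("PBC solves keep the zero-mean gauge", {
  g <- dielectric_grid(make_ion(radius = 0.2), L = 1.6, spacing = 0.1,
                       eps_solvent = 66.6, boundary = "PBC")
  phi <- solve_poisson_fd(g)
  expect_lt(abs(mean(phi)), 1e-8)
})

test_that("FD and FFT solvers agree for a homogeneous vacuum system", {
  spec <- scheme_spec("LS", box_edge_L = 2.0, spacing = 0.05)
  sA <- make_pair(1, 0, d = 0.7)
  sA$atoms$radius <- 0
  g <- dielectric_grid(sA, 2.0, 0.05, eps_solvent = 1, boundary = "PBC")
  eFD <- potential_at_sites(g, solve_poisson_fd(g, tol_energy = 1e-5))[2]
  eFFT <- potential_at_sites(g, solve_poisson_fft(g, "LS", spec))[2]
  expect_lt(abs(eFD - eFFT), 0.5)
  # and both close to the exact periodic pair potential
  kc <- phys_constants()$coulomb_factor
  expect_lt(abs(eFFT - kc * psi("LS", c(0.7, 0, 0), spec)), 0.5)
})

test_that("continuum charging is zero for an uncharged guest", {
  s <- make_ion(q = 0, radius = 0.2)
  spec <- scheme_spec("CB", box_edge_L = 1.6, spacing = 0.1)
  expect_identical(charging_free_energy_continuum(s, spec, "CB"), 0)
})

test_that("grid refinement leaves the polarization correction stable", {
  # raw charging energies carry an O(h) cavity-discretization error, but
  # it cancels between the CB and LS solves entering dG_pol
  ion <- make_ion()
  spec <- scheme_spec("LS", box_edge_L = 1.6)
  coarse <- dG_pol(ion, spec, "LS", spacing = 0.1)
  fine <- dG_pol(ion, spec, "LS", spacing = 0.05)
  expect_lt(abs(fine - coarse), 1)
  # the raw solves themselves converge towards the Born value
  kc <- phys_constants()$coulomb_factor
  born <- -(1 - 1 / 78.4) * kc / (2 * 0.2)
  spec_cb <- scheme_spec("CB", box_edge_L = 1.6)
  e_coarse <- charging_free_energy_continuum(ion, spec_cb, "CB",
                                             spacing = 0.1)
  e_fine <- charging_free_energy_continuum(ion, spec_cb, "CB",
                                           spacing = 0.05)
  expect_lt(abs(e_fine - born), abs(e_coarse - born))
})

test_that("polarization correction is even in the ion charge", {
  # linear-response continuum: for a centrosymmetric cavity the charging
  # free energy is quadratic in q, so dG_pol is invariant under q -> -q
  spec <- scheme_spec("LS", box_edge_L = 1.6, spacing = 0.1)
  plus <- dG_pol(make_ion(q = 1), spec, "LS", spacing = 0.1)
  minus <- dG_pol(make_ion(q = -1), spec, "LS", spacing = 0.1)
  expect_equal(plus, minus, tolerance = 1e-6)
})

test_that("heterogeneous FFT solve matches the FD solver with the matched kernel", {
  # the spectral periodic-Coulomb kernel is the exact inverse of the FD
  # stencil, so the bound-charge (GMRES) route must reproduce the FD
  # solution even at full water-like permittivity contrast
  ion <- make_ion()
  spec <- scheme_spec("LS", box_edge_L = 1.6, spacing = 0.1)
  g <- dielectric_grid(ion, 1.6, 0.1, eps_solvent = 66.6, boundary = "PBC")
  vf <- potential_at_sites(g, solve_poisson_fft(g, "LS", spec))
  vd <- potential_at_sites(g, solve_poisson_fd(g, tol_energy = 1e-5))
  expect_equal(vf, vd, tolerance = 1e-6)
})

test_that("BM continuum polarization correction is negative for a cation", {
  # cutoff truncation underpolarizes the solvent, like periodicity does
  ion <- make_ion()
  spec <- scheme_spec("BM", box_edge_L = 1.6, cutoff_RC = 0.7,
                      spacing = 0.1)
  v <- dG_pol(ion, spec, "BM", spacing = 0.1)
  expect_true(is.finite(v))
  expect_lt(v, 0)
})

test_that("LS polarization correction for a cation is negative and shrinks with L", {
  # periodic underpolarization: |dG_pol| decreases with the box edge
  vals <- vapply(c(1.6, 2.4), function(L)
    dG_pol(make_ion(), scheme_spec("LS", box_edge_L = L), "LS",
           spacing = 0.1), numeric(1))
  expect_true(all(vals < 0))
  expect_lt(abs(vals[2]), abs(vals[1]))
})
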