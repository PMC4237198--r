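spec_bm <- scheme_spec("BM", box_edge_L = 3.8, cutoff_RC = 1.4)
spec_ls <- scheme_spec("LS", box_edge_L = 2.9)

test_that("Coulomb and reaction-field pair functions have the stated form", {
  expect_equal(psi("CB", c(1, 0, 0)), 1)
  expect_equal(psi("CB", c(0, 0.5, 0)), 2)
  expect_error(psi("CB", c(0, 0, 0)), "singular")
  # exact zero at the cutoff and beyond
  expect_identical(psi("BM", c(1.4, 0, 0), spec_bm), 0)
  expect_identical(psi("BM", c(0, 1.6, 0), spec_bm), 0)
  # finite and smoothly varying on (0, R_C]
  r <- seq(0.05, 1.4, by = 0.005)
  v <- psi("BM", cbind(r, 0, 0), spec_bm)
  expect_true(all(is.finite(v)))
  expect_true(all(diff(v) < 0))   # monotone decay up to the cutoff
})

test_that("lattice-summation pair function is periodic and alpha-independent", {
  r0 <- c(0.31, -0.42, 0.77)
  p0 <- psi("LS", r0, spec_ls)
  expect_lt(abs(psi("LS", r0 + c(2.9, 0, 0), spec_ls) - p0), 1e-8)
  expect_lt(abs(psi("LS", r0 - c(0, 2.9, 2.9), spec_ls) - p0), 1e-8)
  spec_b <- scheme_spec("LS", box_edge_L = 2.9, ewald_alpha_factor = 5)
  expect_lt(abs(psi("LS", r0, spec_b) - p0), 1e-6)
})

test_that("lattice-summation pair function matches a naive Ewald oracle", {
  pts <- rbind(c(0.3, 0, 0), c(0.9, 0.4, -0.2), c(1.4, 1.4, 1.4),
               c(-0.05, 0.02, 0.01))
  for (k in seq_len(nrow(pts))) {
    expect_lt(abs(psi("LS", pts[k, ], spec_ls) -
                    naive_ewald(pts[k, ], 2.9)), 1e-6)
  }
  # r -> 0 limit reproduces the cubic-lattice self constant
  r <- 1e-5
  expect_equal((psi("LS", c(r, 0, 0), spec_ls) - 1 / r) * 2.9,
               phys_constants()$wigner_cubic, tolerance = 1e-4)
})

test_that("effective-minus-Coulomb kernel is bounded at short range", {
  for (r in c(1e-4, 1e-3, 1e-2, 0.1)) {
    expect_lt(abs(psi_minus_coulomb("LS", c(r, 0, 0), spec_ls)), 10)
    expect_lt(abs(psi_minus_coulomb("BM", c(r, 0, 0), spec_bm)), 10)
  }
  # consistency with the direct difference at moderate r
  r <- c(0.4, 0.1, -0.2)
  expect_equal(psi_minus_coulomb("LS", r, spec_ls),
               psi("LS", r, spec_ls) - 1 / sqrt(sum(r^2)),
               tolerance = 1e-10)
})

test_that("guest-environment energies follow the charge scaling", {
  kc <- phys_constants()$coulomb_factor
  pair <- make_pair(1, 1, d = 1, groups = c("guest", "host"))
  expect_equal(guest_env_energy(pair, 1, "CB"), kc, tolerance = 1e-12)
  expect_equal(guest_env_energy(pair, 0.5, "CB"), kc / 2, tolerance = 1e-12)
  expect_identical(guest_env_energy(pair, 0, "CB"), 0)
  # uncharged host: zero at any lambda
  capo <- build_complex(fixture_recipe(host = "CAPO", guest = "MAM"))
  expect_identical(guest_env_energy(capo, 1, "CB"), 0)
})

test_that("guest-host correction vanishes for CAPO and matches the rigid limit", {
  spec <- scheme_spec("LS", box_edge_L = 3.8)
  capo <- build_complex(fixture_recipe(host = "CAPO", guest = "MAM"))
  expect_equal(dG_hs(capo, "LS", spec), 0, tolerance = 1e-12)
  cpos <- build_complex(fixture_recipe(host = "CPOS", guest = "MAM"))
  got <- dG_hs(cpos, "LS", spec)
  rigid <- guest_env_energy(cpos, 1, "CB") -
    guest_env_energy(cpos, 1, "LS", spec)
  expect_equal(got, rigid, tolerance = 1e-9)
  # second, coarser TI route gives the same answer (linearity in lambda)
  expect_equal(dG_hs(cpos, "LS", spec, lambdas = c(0, 1)), rigid,
               tolerance = 1e-9)
})

test_that("guest-host correction signs follow host charge", {
  spec <- scheme_spec("LS", box_edge_L = 3.8)
  cpos <- build_complex(fixture_recipe(host = "CPOS", guest = "MAM"))
  cneg <- build_complex(fixture_recipe(host = "CNEG", guest = "MAM"))
  expect_gt(dG_hs(cpos, "LS", spec), 0)   # like-charged pair
  expect_lt(dG_hs(cneg, "LS", spec), 0)   # oppositely charged
  specb <- scheme_spec("BM", box_edge_L = 3.8, cutoff_RC = 1.4)
  expect_gt(dG_hs(cpos, "BM", specb), 0)
  expect_lt(dG_hs(cneg, "BM", specb), 0)
})

test_that("excluded-pair correction honours the documented limits", {
  spec <- scheme_spec("LS", box_edge_L = 3.8)
  # no exclusions / monoatomic guest
  expect_identical(dG_excl(make_ion(), "LS", spec), 0)
  lone <- make_pair(1, 1, d = 0.5)      # no bonds -> empty exclusion list
  expect_identical(dG_excl(lone, "LS", spec), 0)
  # fixture guests: small magnitude with benchmark-like parameters
  for (g in c("MAM", "ACE")) {
    cplx <- build_complex(fixture_recipe(host = "CAPO", guest = g))
    expect_lt(abs(dG_excl(cplx, "LS", spec)), 1)
    expect_lt(abs(dG_excl(cplx, "BM",
                          scheme_spec("BM", box_edge_L = 3.8,
                                      cutoff_RC = 1.4))), 1)
  }
})

test_that("excluded-pair correction scales with box size as the scheme dictates", {
  bonded <- make_pair(0.5, 0.5, d = 0.15, bond = TRUE)
  vals_ls <- vapply(c(2.9, 3.8, 6), function(L)
    dG_excl(bonded, "LS", scheme_spec("LS", box_edge_L = L)), numeric(1))
  expect_true(all(diff(abs(vals_ls)) < 0))   # magnitude decays with L
  vals_bm <- vapply(c(2.9, 3.8, 6), function(L)
    dG_excl(bonded, "BM", scheme_spec("BM", box_edge_L = L,
                                      cutoff_RC = 1.4)), numeric(1))
  expect_lt(diff(range(vals_bm)), 1e-10)     # independent of L
})
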