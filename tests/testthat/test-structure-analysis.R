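test_that("ideal-gas waters give a flat radial distribution", {
  L <- 3
  set.seed(21)
  frames <- lapply(1:30, function(i)
    list(waters = matrix(stats::runif(3 * 400, 0, L), ncol = 3)))
  prof <- radial_distribution(frames, bin_width = 0.1, L = L,
                              center = c(L, L, L) / 2)
  sel <- prof$r > 0.3 & prof$r < L / 2
  # per-bin Poisson noise: counts ~ rho * shell volume * n_frames
  expect_true(all(abs(prof$g[sel] - 1) <
                    3 / sqrt(prof$counts[sel] * 30 + 1)))
  # all-image counting stays flat beyond L/2 too
  sel2 <- prof$r > L / 2 & prof$r < sqrt(3) * L / 2 * 0.95
  expect_lt(mean(abs(prof$g[sel2] - 1)), 0.1)
})

test_that("excluded-core systems show g = 0 below the core radius", {
  L <- 3; r0 <- 0.8
  set.seed(22)
  pts <- matrix(stats::runif(3 * 4000, 0, L), ncol = 3)
  ctr <- c(L, L, L) / 2
  d <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  frames <- list(list(waters = pts[d > r0, ][1:400, ]))
  prof <- radial_distribution(frames, bin_width = 0.05, L = L, center = ctr)
  expect_true(all(prof$g[prof$r < r0 - 0.05] == 0))
  expect_gt(mean(prof$g[prof$r > r0 & prof$r < L / 2]), 0.5)
})

test_that("image-counted histogram integrates to the image population", {
  L <- 2.5
  set.seed(23)
  nw <- 500
  frames <- lapply(1:5, function(i)
    list(waters = matrix(stats::runif(3 * nw, 0, L), ncol = 3)))
  prof <- radial_distribution(frames, bin_width = 0.05, L = L,
                              center = c(L, L, L) / 2)
  rmax <- sqrt(3) * L / 2
  got <- sum(prof$counts)
  expected <- nw * (4 / 3) * pi * rmax^3 / L^3
  expect_equal(got, expected, tolerance = 0.01)
})

test_that("radial polarization reports dipole orientation with sign", {
  L <- 3; ctr <- c(L, L, L) / 2
  set.seed(24)
  wat <- matrix(stats::runif(3 * 500, 0, L), ncol = 3)
  d <- sweep(wat, 2, ctr); d <- d - L * round(d / L)
  r <- sqrt(rowSums(d^2))
  outward <- d / r
  mu <- phys_constants()$mu_spc
  # fully outward-aligned dipoles: P equals mu * local count density
  prof <- radial_polarization(list(list(waters = wat, dipoles = outward)),
                              bin_width = 0.1, L = L, center = ctr)
  counts <- radial_distribution(list(list(waters = wat)), bin_width = 0.1,
                                L = L, center = ctr)$counts
  sel <- counts > 0 & prof$r < L / 2
  expect_equal(prof$P[sel],
               mu * counts[sel] / (4 * pi * prof$r[sel]^2 * 0.1),
               tolerance = 1e-9)
  # inward dipoles flip the sign
  prof_in <- radial_polarization(list(list(waters = wat,
                                           dipoles = -outward)),
                                 bin_width = 0.1, L = L, center = ctr)
  expect_true(all(prof_in$P[sel] <= 0))
  # random orientations average to zero within noise
  set.seed(25)
  rnd <- matrix(stats::rnorm(3 * 500), ncol = 3)
  rnd <- rnd / sqrt(rowSums(rnd^2))
  frames <- lapply(1:20, function(i) list(waters = wat, dipoles = rnd[sample(500), ]))
  prof_r <- radial_polarization(frames, bin_width = 0.25, L = L,
                                center = ctr)
  selr <- prof_r$r > 0.5 & prof_r$r < L / 2
  sigma <- mu * sqrt(counts[1] + 1)  # loose per-bin scale
  expect_lt(max(abs(prof_r$P[selr])), 1)
})

test_that("Born polarization analog follows its closed form", {
  expect_identical(born_polarization(0.7, 2, eps = 1), 0)
  expect_equal(born_polarization(1, 1), 1 / (4 * pi) * (1 - 1 / 66.6),
               tolerance = 1e-12)
  expect_equal(born_polarization(1, 1), 0.0784, tolerance = 1e-3)
  expect_equal(born_polarization(0.5, 2), 2 * born_polarization(0.5, 1),
               tolerance = 1e-12)
  expect_error(born_polarization(0, 1))
})

test_that("a forced orientation flip at the cutoff leaves a polarization dip", {
  L <- 4; rc <- 1.4; ctr <- c(L, L, L) / 2
  set.seed(26)
  wat <- matrix(stats::runif(3 * 3000, 0, L), ncol = 3)
  d <- sweep(wat, 2, ctr); d <- d - L * round(d / L)
  r <- sqrt(rowSums(d^2))
  outward <- d / r
  # emulate cutoff truncation: aligned inside R_C, randomized outside
  rnd <- matrix(stats::rnorm(3 * 3000), ncol = 3)
  rnd <- rnd / sqrt(rowSums(rnd^2))
  dip <- outward
  dip[r > rc, ] <- rnd[r > rc, ]
  prof <- radial_polarization(list(list(waters = wat, dipoles = dip)),
                              bin_width = 0.1, L = L, center = ctr)
  inside <- mean(prof$P[prof$r > rc - 0.4 & prof$r < rc])
  outside <- mean(prof$P[prof$r > rc & prof$r < rc + 0.4])
  expect_gt(inside, 3 * abs(outside))
})
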