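test_that("ledger assembly reproduces benchmark anchor rows", {
  expect_equal(assemble_corrected(-4.4, -71.2, -75.4, 0.0, -0.2,
                                  environment = "CAPO")$corrected,
               -151.2, tolerance = 1e-9)
  expect_equal(assemble_corrected(102.8, -146.4, -77.1, 102.6, -0.1,
                                  environment = "CPOS")$corrected,
               -18.2, tolerance = 1e-9)
  expect_identical(assemble_corrected(0, 0, 0, 0, 0)$corrected, 0)
})

test_that("binding contributions difference in-host and in-water ledgers", {
  lw <- assemble_corrected(-172.6, -75.8, -77.8, 0, -0.2, guest = "MAM",
                           environment = "W", scheme = "LS,ss")
  lh <- assemble_corrected(-24.7, -49.2, -77.1, 0, -0.1, guest = "MAM",
                           environment = "CAPO", scheme = "LS,l")
  b <- binding_contribution(lw, lh)
  expect_equal(b$ddG_raw, 147.9, tolerance = 1e-9)
  expect_equal(binding_contribution(lw, lw)$ddG_cor, 0)
  lwl <- assemble_corrected(-197.8, -51.3, -79.2, 0, -0.1, guest = "MAM",
                            environment = "W", scheme = "LS,l")
  lhl <- assemble_corrected(102.8, -146.4, -77.1, 102.6, -0.1,
                            guest = "MAM", environment = "CPOS",
                            scheme = "LS,l")
  expect_equal(binding_contribution(lwl, lhl)$ddG_raw, 300.6,
               tolerance = 1e-9)
  lw2 <- lw; lw2$guest <- "ACE"
  expect_error(binding_contribution(lw2, lh), "different guests")
})

test_that("combination statistics reproduce the benchmark averages", {
  lw <- benchmark_ledgers("MAM", "W")
  lcapo <- benchmark_ledgers("MAM", "CAPO")
  st <- combination_stats(lw, lcapo, "LS")
  expect_equal(st$n, 16)
  expect_equal(st$mean, 176.0, tolerance = 0.1 / 176)
  lcneg <- benchmark_ledgers("MAM", "CNEG")
  stu <- combination_stats(lw, lcneg, "LS+BM")
  expect_equal(stu$n, 20)
  expect_equal(round(stu$mean, 1), -66.6)
  # union mean is the 16/4-weighted mean of the per-scheme means
  sls <- combination_stats(lw, lcneg, "LS")
  sbm <- combination_stats(lw, lcneg, "BM")
  expect_equal(stu$mean, (16 * sls$mean + 4 * sbm$mean) / 20,
               tolerance = 1e-12)
  # degenerate case
  one <- combination_stats(lw[1], lcapo[1], "LS")
  expect_equal(one$rmsd, 0)
})

test_that("consistency rmsd matches the published spreads", {
  t2 <- benchmark_charging_table()
  raw_w <- t2$raw[t2$guest == "MAM" & t2$environment == "W"]
  cor_w <- t2$corrected[t2$guest == "MAM" & t2$environment == "W"]
  expect_equal(round(consistency_rmsd(raw_w), 1), 9.0)
  expect_equal(round(consistency_rmsd(cor_w), 1), 1.4)
  expect_equal(consistency_rmsd(c(5, 5, 5)), 0)
  expect_error(consistency_rmsd(3), "2 values")
})

test_that("solvent/host decomposition extracts the cross term", {
  lam <- seq(0, 1, 0.1)
  # rigid complex: cross term linear in lambda, solvent-free synthetic case
  cpos <- build_complex(fixture_recipe(host = "CPOS", guest = "MAM"))
  spec <- scheme_spec("LS", box_edge_L = 3.8)
  ugh <- guest_env_energy(cpos, 1, "LS", spec)   # dU_GH/dlambda, constant
  total <- lambda_series(lam, ugh + 10 * lam)    # plus a fake solvent part
  guest_only <- lambda_series(lam, 10 * lam)
  host_only <- lambda_series(lam, rep(0, 11))
  d <- decompose_charging(total, guest_only, host_only,
                          dG_hs = dG_hs(cpos, "LS", spec))
  expect_equal(d$raw_host, ugh, tolerance = 1e-9)
  expect_equal(d$raw_solvent, trapezoid_ti(guest_only)$value,
               tolerance = 1e-9)
  expect_equal(d$cor_host, guest_env_energy(cpos, 1, "CB"),
               tolerance = 1e-9)
  # zero host charges: everything is solvent
  d0 <- decompose_charging(total, total,
                           lambda_series(lam, rep(0, 11)))
  expect_equal(d0$raw_host, 0)
  expect_equal(d0$raw_solvent, trapezoid_ti(total)$value)
})

test_that("benchmark decomposition tables satisfy the additivity identities", {
  t2 <- benchmark_charging_table()
  t3 <- benchmark_decomposition_table()
  m <- merge(t3, t2, by.x = c("guest", "host", "scheme"),
             by.y = c("guest", "environment", "scheme"))
  expect_equal(nrow(m), 48)
  expect_lt(max(abs(m$raw_solvent + m$raw_host - m$raw)), 0.15)
  expect_lt(max(abs(m$cor_solvent + m$cor_host - m$corrected)), 0.15)
  # corrected host contribution is scheme/box invariant per complex
  for (g in c("MAM", "ACE")) for (h in c("CHB", "CPOS", "CNEG")) {
    span <- diff(range(t3$cor_host[t3$guest == g & t3$host == h]))
    expect_lte(span, 1.0)
  }
  span_cneg <- diff(range(t3$cor_host[t3$guest == "MAM" &
                                        t3$host == "CNEG"]))
  expect_lte(span_cneg, 0.6)
})

test_that("equisized-box raw differences track the corrected mean best", {
  t2 <- benchmark_charging_table()
  raw <- function(g, e, s) t2$raw[t2$guest == g & t2$environment == e &
                                    t2$scheme == s]
  for (g in c("MAM", "ACE")) for (h in c("CAPO", "CHB")) {
    st <- combination_stats(benchmark_ledgers(g, "W"),
                            benchmark_ledgers(g, h), "LS")
    equis <- raw(g, h, "LS,l") - raw(g, "W", "LS,l")
    mixed <- raw(g, h, "LS,l") - raw(g, "W", "LS,ss")
    expect_lt(abs(equis - st$mean), abs(mixed - st$mean))
  }
})
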