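# Two-state dispersion forward models and dataset simulation.

test_that("Carver-Richards agrees with the Bloch-McConnell propagator on the stress grid", {
  nu <- c(25, 50, 75, 100, 150, 200, 300, 400, 500, 600, 700, 800, 900, 1000)
  grid <- expand.grid(pB = c(0.005, 0.02, 0.1),
                      kex = c(500, 2200, 10000),
                      dw = c(100, 500, 1500))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    a <- r2eff_two_state_cpmg(g$pB, g$kex, g$dw, 15, nu, "carver_richards")
    b <- r2eff_two_state_cpmg(g$pB, g$kex, g$dw, 15, nu, "numerical")
    expect_lt(max(abs(a - b)), 0.05)
    # dispersion curves decay monotonically with refocusing frequency
    expect_true(all(diff(b) <= 1e-9))
  }
})

test_that("no exchange means flat CPMG curves at R2,0", {
  nu <- c(50, 200, 800)
  expect_equal(r2eff_two_state_cpmg(0.02, 2000, 0, 17.3, nu),
               rep(17.3, 3))
  expect_equal(r2eff_two_state_cpmg(0.02, 2000, 0, 17.3, nu, "numerical"),
               rep(17.3, 3))
})

test_that("spin-lock rates: no-exchange limit, analytic-numerical agreement, saturation", {
  # dw = 0, on-resonance: R1rho = R2,0 (theta = 90 degrees)
  expect_equal(r1rho_two_state(0.02, 2000, 0, 16, 1.2, 2000, 0, "analytic"),
               16, tolerance = 1e-9)

  # analytic vs numerical < 5% relative over the fast/intermediate grid
  for (kex in c(2000, 5000, 20000)) for (dw in c(500, 1000, 2000)) {
    if (kex < dw) next
    for (off in c(0, 300)) {
      an <- r1rho_two_state(0.03, kex, dw, 14, 1.5, 1500, off, "analytic")
      nm <- r1rho_two_state(0.03, kex, dw, 14, 1.5, 1500, off, "numerical")
      expect_lt(abs(an / nm - 1), 0.05)
    }
  }

  # exchange contribution vanishes as the spin-lock strength grows
  rexes <- vapply(c(500, 1000, 2000, 4000), function(w1)
    r1rho_two_state(0.02, 3000, 800, 14, 1.5, w1, 0, "numerical") - 14,
    numeric(1))
  expect_true(all(diff(rexes) < 0))
})

test_that("dataset simulation is deterministic and honest about its truth", {
  spec <- canonical_dispersion_spec("WT", noise_sd = 0)
  d1 <- simulate_dispersion(spec, seed = 5)
  d2 <- simulate_dispersion(spec, seed = 5)
  expect_identical(d1$rate_s, d2$rate_s)

  specn <- canonical_dispersion_spec("WT", noise_sd = 0.3)
  dn1 <- simulate_dispersion(specn, seed = 6)
  dn2 <- simulate_dispersion(specn, seed = 6)
  expect_identical(dn1$rate_s, dn2$rate_s)
  expect_false(identical(dn1$rate_s, simulate_dispersion(specn, 7)$rate_s))
  expect_true(all(dn1$error_s == 0.3))

  # a zero-shift residue gives a flat curve at its r20
  spec0 <- dispersion_spec(pB = 0.02, kex = 2200,
                           dw_ppm = c("10" = 0.0001),
                           r20 = matrix(12, 1, 1,
                                        dimnames = list("10", "600")),
                           fields_mhz = 600,
                           nu_cpmg_grid = c(50, 100, 400, 800))
  d0 <- simulate_dispersion(spec0, seed = 1)
  expect_lt(max(d0$rate_s) - min(d0$rate_s), 1e-4)

  expect_error(dispersion_spec(0.02, 2200, c("1" = 1),
                               matrix(12, 1, 1), 600, c(50), noise_sd = -1))
})

test_that("the model-free Rex estimate matches curve extremes", {
  spec <- canonical_dispersion_spec("WT", noise_sd = 0)
  d <- simulate_dispersion(spec, seed = 1)
  rx <- rex_estimate(d)
  # noiseless: exactly the forward-model difference, averaged over fields
  for (i in seq_len(nrow(rx))) {
    res <- rx$residue[i]
    vals <- vapply(spec$fields_mhz, function(f) {
      dw <- ppm_to_rad(spec$dw_ppm[as.character(res)], f)
      r20 <- spec$r20[as.character(res), as.character(f)]
      r <- r2eff_two_state_cpmg(spec$pB, spec$kex, dw, r20,
                                range(spec$nu_cpmg_grid), "numerical")
      r[1] - r[2]
    }, numeric(1))
    expect_equal(rx$rex_s[i], mean(vals), tolerance = 1e-9)
  }

  # two identical curves at two fields: the average equals either
  spec2 <- dispersion_spec(pB = 0.02, kex = 2200, dw_ppm = c("7" = 2),
                           r20 = matrix(c(12, 12), 1, 2,
                                        dimnames = list("7", c("600", "600.0001"))),
                           fields_mhz = c(600, 600.0001),
                           nu_cpmg_grid = c(50, 100, 400, 800))
  d2 <- simulate_dispersion(spec2, seed = 1)
  rx2 <- rex_estimate(d2)
  one <- d2[d2$field_mhz == 600, ]
  expect_equal(rx2$rex_s,
               one$rate_s[which.min(one$nu_cpmg_hz)] -
                 one$rate_s[which.max(one$nu_cpmg_hz)],
               tolerance = 1e-6)
})
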