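# Global two-state fitting: exact recovery, model selection, and
# degeneracy behaviour.

test_that("noiseless self-generated CPMG data are recovered exactly", {
  spec <- canonical_dispersion_spec("WT", noise_sd = 0)
  spec$spinlock_grid <- NULL
  d <- simulate_dispersion(spec, seed = 1)
  fit <- global_fit_two_state(d, seed = 1)
  expect_equal(fit$kex, 2200, tolerance = 1e-6)
  expect_equal(fit$pB, 0.02, tolerance = 1e-6)
  expect_lt(fit$chi2_reduced, 1e-6)
  expect_equal(unname(fit$dw_ppm["66"]), 3.5, tolerance = 1e-5)
})

test_that("fitting across forward-model routes recovers parameters within 2%", {
  # data generated by the numerical propagators, fitted with the
  # analytic models (the default) -- and the reverse direction via a
  # carver-richards-generated set
  spec <- canonical_dispersion_spec("WT", noise_sd = 0)
  spec$spinlock_grid <- NULL
  d_num <- simulate_dispersion(spec, seed = 2)
  f1 <- global_fit_two_state(d_num, seed = 2)
  expect_lt(abs(f1$kex / 2200 - 1), 0.02)
  expect_lt(abs(f1$pB / 0.02 - 1), 0.02)

  d_cr <- d_num
  for (res in names(spec$dw_ppm)) for (f in spec$fields_mhz) {
    sel <- d_cr$residue == as.integer(res) & d_cr$field_mhz == f
    d_cr$rate_s[sel] <- r2eff_two_state_cpmg(
      spec$pB, spec$kex, ppm_to_rad(spec$dw_ppm[res], f),
      spec$r20[res, as.character(f)], d_cr$nu_cpmg_hz[sel],
      "carver_richards")
  }
  f2 <- global_fit_two_state(d_cr, seed = 2)
  expect_lt(abs(f2$kex / 2200 - 1), 0.02)
  expect_lt(abs(f2$pB / 0.02 - 1), 0.02)
})

test_that("model comparison prefers the true model", {
  # null truth: flat curves
  spec0 <- dispersion_spec(pB = 0.02, kex = 2200,
                           dw_ppm = c("5" = 1e-6, "9" = 1e-6),
                           r20 = matrix(c(12, 14), 2, 1,
                                        dimnames = list(c("5", "9"), "600")),
                           fields_mhz = 600,
                           nu_cpmg_grid = c(25, 50, 100, 200, 400, 600, 1000),
                           noise_sd = 0.2)
  d0 <- simulate_dispersion(spec0, seed = 3)
  f0_flat <- fit_flat_model(d0)
  f0_two <- global_fit_two_state(d0, seed = 3)
  expect_lte(f0_two$chi2, f0_flat$chi2 + 1e-6)
  cmp0 <- model_compare(d0, f0_flat, f0_two)
  expect_equal(cmp0$preferred, "1-state")

  # planted exchange: 2-state preferred in >= 19/20 seeded regenerations
  specx <- dispersion_spec(pB = 0.02, kex = 2200,
                           dw_ppm = c("5" = 600 / (0.1013 * 600 * 2 * pi),
                                      "9" = 450 / (0.1013 * 600 * 2 * pi)),
                           r20 = matrix(c(12, 14), 2, 1,
                                        dimnames = list(c("5", "9"), "600")),
                           fields_mhz = 600,
                           nu_cpmg_grid = c(25, 50, 100, 200, 400, 600, 1000),
                           noise_sd = 0.3)
  wins <- 0
  for (s in 1:20) {
    dx <- simulate_dispersion(specx, seed = 100 + s)
    cmp <- model_compare(dx, fit_flat_model(dx),
                         global_fit_two_state(dx, seed = s))
    if (cmp$preferred == "2-state") wins <- wins + 1
  }
  expect_gte(wins, 19)
})

test_that("the fast-exchange degeneracy yields honestly wide intervals", {
  # well-conditioned (intermediate exchange) reference
  mk <- function(kex, pB, dw_ppm, noise) {
    dispersion_spec(pB = pB, kex = kex,
                    dw_ppm = c("5" = dw_ppm, "9" = dw_ppm * 0.75),
                    r20 = matrix(c(12, 14), 2, 1,
                                 dimnames = list(c("5", "9"), "600")),
                    fields_mhz = 600,
                    nu_cpmg_grid = c(25, 50, 100, 150, 200, 300, 400, 600,
                                     800, 1000),
                    noise_sd = noise)
  }
  d_good <- simulate_dispersion(mk(2200, 0.02, 3.5, 0.05), seed = 4)
  f_good <- global_fit_two_state(d_good, seed = 4, n_boot = 30)
  w_good <- diff(unname(f_good$ci$pB)) / f_good$pB

  # deep fast exchange: only the product pB * dw^2 is determined
  d_fast <- simulate_dispersion(mk(30000, 0.02, 3.5, 0.05), seed = 4)
  f_fast <- global_fit_two_state(d_fast, seed = 4, n_boot = 30)
  w_fast <- diff(unname(f_fast$ci$pB)) / f_fast$pB
  expect_gt(w_fast / w_good, 5)
})
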