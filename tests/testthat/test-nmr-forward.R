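# Ensemble-averaged shifts, CSPs, exchange mapping, forward Rex, and
# model-free heteronuclear NOE.

tab <- function(res, h, n) data.frame(residue = res, dH_ppm = h, dN_ppm = n)

test_that("ensemble shift averaging is a population-weighted linear map", {
  a <- tab(1:2, c(8.0, 7.5), c(120, 115))
  b <- tab(1:2, c(8.2, 7.7), c(122, 117))
  avg <- ensemble_average_shifts(c(0.5, 0.5), list(a, b))
  expect_equal(avg$dH_ppm, c(8.1, 7.6))
  expect_equal(avg$dN_ppm, c(121, 116))

  expect_equal(ensemble_average_shifts(1, list(a)), a)

  # linearity: affine transform of inputs transforms the output
  f <- function(s) tab(s$residue, 2 * s$dH_ppm + 1, 0.5 * s$dN_ppm - 3)
  avg_t <- ensemble_average_shifts(c(0.3, 0.7), list(f(a), f(b)))
  avg_o <- ensemble_average_shifts(c(0.3, 0.7), list(a, b))
  expect_equal(avg_t$dH_ppm, 2 * avg_o$dH_ppm + 1, tolerance = 1e-12)
  expect_equal(avg_t$dN_ppm, 0.5 * avg_o$dN_ppm - 3, tolerance = 1e-12)

  expect_warning(ensemble_average_shifts(c(0.5, 0.5),
                                         list(a, tab(1, 8.2, 122))),
                 "omitted")
})

test_that("combined CSP follows the weighted euclidean formula", {
  a <- tab(1, 8.0, 120)
  b <- tab(1, 8.1, 121)
  expect_equal(csp(a, a)$csp_ppm, 0)
  expect_equal(csp(a, b)$csp_ppm, sqrt(0.1^2 + 0.14^2), tolerance = 1e-12)
  expect_equal(csp(a, b)$csp_ppm, csp(b, a)$csp_ppm)
  # triangle inequality per residue
  c3 <- tab(1, 7.8, 119)
  expect_lte(csp(a, c3)$csp_ppm, csp(a, b)$csp_ppm + csp(b, c3)$csp_ppm)
  expect_error(csp(a, tab(2, 8, 120)), "shared")
})

test_that("largest predicted mutant CSPs localise to the 70s loop residues", {
  wt <- build_canonical_model("WT")
  mut <- build_canonical_model("D66A")
  avg_of <- function(m) ensemble_average_shifts(
    unname(m$pops), lapply(m$macrostates, function(s) s$shifts))
  prof <- csp(avg_of(wt), avg_of(mut))
  loop <- prof$residue %in% 65:77
  # the planted shift differences live on the 70s loop
  expect_gt(min(prof$csp_ppm[prof$residue %in% c(66, 71, 72, 74)]),
            max(prof$csp_ppm[!loop]))
})

test_that("two-state mapping reproduces aggregate populations and chain kinetics", {
  m <- build_canonical_model("WT")
  mp <- map_to_exchange_model(m)
  expect_equal(mp$pA, 0.70, tolerance = 1e-9)
  expect_equal(mp$pB, 0.30, tolerance = 1e-9)
  expect_gt(mp$kex_s, 0)

  # kex from MFPTs equals the relaxation eigenvalue of a true 2-state chain
  k12 <- 0.8; k21 <- 0.4   # per ms
  Q <- matrix(c(-k12, k12, k21, -k21), 2, byrow = TRUE)
  pi2 <- c(k21, k12) / (k12 + k21)
  mf <- c(msmdesign:::mfpt_generator(Q, pi2, 1, 2),
          msmdesign:::mfpt_generator(Q, pi2, 2, 1))
  kex_mfpt <- 1000 / mf[1] + 1000 / mf[2]
  relax_eig <- 1000 * (-sort(Re(eigen(Q, only.values = TRUE)$values))[1])
  expect_equal(kex_mfpt, relax_eig, tolerance = 1e-9)

  # degenerate split errors
  m2 <- m
  m2$loop70 <- rep("closed", 5)
  expect_error(map_to_exchange_model(m2), "group")
})

test_that("forward Rex matches the fast-exchange closed form and is large for loop residues", {
  mp <- structure(list(pA = 0.98, pB = 0.02, kex_s = 10000,
                       dw = data.frame(residue = c(1, 2),
                                       dw_ppm = c(0, 0.5),
                                       dw_rad = c(0, 200)),
                       field_mhz = 600), class = "exchange_mapping")
  rx <- rex_forward(mp, nu_min = 10, nu_max = 10000)
  expect_equal(rx$rex_s[1], 0)
  expect_equal(rx$rex_fast_s[2], 0.98 * 0.02 * 200^2 / 10000,
               tolerance = 1e-9)  # 0.0784
  expect_equal(rx$rex_s[2], 0.0784, tolerance = 0.03)

  # fast-exchange limit: closed form vs numerical difference < 5 %
  for (dw in c(300, 600)) {
    mp$dw$dw_rad[2] <- dw
    mp$kex_s <- 10 * dw
    rx2 <- rex_forward(mp, nu_min = 10, nu_max = 1e5)
    expect_lt(abs(rx2$rex_s[2] / rx2$rex_fast_s[2] - 1), 0.05)
  }

  # canonical landscape kinetics over-predict exchange broadening:
  # hundreds per second for the planted 70s residues
  m <- build_canonical_model("WT")
  rx3 <- rex_forward(map_to_exchange_model(m))
  expect_true(all(rx3$rex_s[rx3$residue %in% c(66, 71, 72, 74)] > 100))
})

test_that("model-free NOE matches the rigid-rotor oracle and behaves monotonically", {
  for (tc in c(4, 8, 15)) {
    got <- noe_from_modelfree(1, tc, 0, 600)$noe
    expect_equal(got, noe_rigid_oracle(tc, 600), tolerance = 1e-9)
  }

  # NOE non-increasing as S2 decreases (tau_e = 50 ps)
  s2_grid <- seq(1, 0.4, by = -0.1)
  noes <- vapply(s2_grid, function(s2)
    noe_from_modelfree(s2, 8, 50, 600)$noe, numeric(1))
  expect_true(all(diff(noes) <= 1e-9))

  # slow-tumbling plateau
  n50 <- noe_from_modelfree(1, 50, 0, 600)$noe
  n100 <- noe_from_modelfree(1, 100, 0, 600)$noe
  expect_lt(abs(n100 / n50 - 1), 0.01)

  expect_error(noe_from_modelfree(1.2, 8), "S2")
  expect_error(noe_from_modelfree(0.8, 1, tau_e = 2000), "tau_e")
})
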