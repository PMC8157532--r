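# Spectral lumping, MFPTs, and trajectory bootstrap.

make_est <- function(T, pi, lag = 1L) {
  structure(list(T = T, pi = pi, lag = lag,
                 active_set = seq_len(nrow(T)), loglik = NA_real_),
            class = "msm_estimate")
}

test_that("MFPT solves the first-passage system", {
  T2 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  est <- make_est(T2, c(0.5, 0.5))
  expect_equal(mfpt(est, 1, 2, timestep = 1), 10, tolerance = 1e-12)

  # Monte-Carlo first-passage oracle on the canonical WT macro chain
  # sampled at 50 us
  m <- wt_macro_model()
  P <- msmdesign:::expm_db(m$Q, m$pops, 0.05)
  est5 <- make_est(P, m$pops)
  sol <- mfpt(est5, c(1, 2), c(4, 5), timestep = 0.05)  # ms
  mc <- mc_mfpt(P, m$pops, c(1, 2), c(4, 5), n_samples = 5000,
                max_steps = 4000, seed = 99)
  expect_lt(abs(sol - mc["mean"] * 0.05), 3 * mc["se"] * 0.05)

  expect_error(mfpt(est5, 1, 1), "disjoint|intersect")
})

test_that("lumping the canonical microstate chain recovers the planted groups", {
  m <- expand_to_microstates(build_canonical_model("WT"), 20)
  ts <- simulate_dtrajs(m, 50, 10000, seed = 13)
  est <- estimate_reversible_T(count_transitions(ts, lag = 1))
  lump <- pcca_lump(est, 5, timestep = m$timestep_ns * 1e-6)
  expect_equal(sum(lump$macro_pi), 1, tolerance = 1e-9)
  expect_equal(ari(lump$membership, m$micro_to_macro[est$active_set]), 1)
  expect_true(all(diag(lump$mfpt_matrix) == 0))

  # identity lumping at n_macro = n_states
  small <- make_est(matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE),
                    c(0.6, 0.4))
  idl <- pcca_lump(small, 2)
  expect_equal(sort(unique(idl$membership)), 1:2)
  expect_setequal(idl$macro_pi, small$pi)
})

test_that("lumping is invariant under microstate relabelling", {
  m <- expand_to_microstates(build_canonical_model("WT"), 6)
  ts <- simulate_dtrajs(m, 30, 5000, seed = 17)
  est <- estimate_reversible_T(count_transitions(ts, lag = 1))
  lump <- pcca_lump(est, 5, timestep = 1)

  set.seed(18)
  perm <- sample(30)
  dtrajs_p <- lapply(ts$dtrajs, function(d) perm[d])
  est_p <- estimate_reversible_T(count_transitions(dtrajs_p, lag = 1))
  lump_p <- pcca_lump(est_p, 5, timestep = 1)
  # macro populations identical up to macrostate reordering
  expect_equal(sort(lump$macro_pi), sort(lump_p$macro_pi), tolerance = 1e-9)
  # and memberships agree through the permutation
  expect_equal(ari(lump$membership, lump_p$membership[perm]), 1)
})

test_that("trajectory bootstrap gives consistent, seed-stable intervals", {
  m <- expand_to_microstates(build_canonical_model("WT"), 5)
  ts <- simulate_dtrajs(m, 20, 4000, seed = 23)
  b1 <- bootstrap_msm(ts, lag = 1, n_macro = 5, n_boot = 25, seed = 7,
                      timestep = m$timestep_ns * 1e-6)
  b2 <- bootstrap_msm(ts, lag = 1, n_macro = 5, n_boot = 25, seed = 7,
                      timestep = m$timestep_ns * 1e-6)
  expect_identical(b1$ci$pop, b2$ci$pop)
  expect_true(all(b1$ci$pop[, "lower"] <= b1$macro_pi + 1e-9))

  # single trajectory: degenerate resampling, zero-width intervals
  ts1 <- simulate_dtrajs(m, 1, 4000, seed = 29)
  bs <- bootstrap_msm(ts1, lag = 1, n_macro = 5, n_boot = 10, seed = 1,
                      timestep = 1)
  expect_equal(bs$ci$pop[, "lower"], bs$ci$pop[, "upper"], tolerance = 1e-12)
})

test_that("bootstrap intervals cover the planted population at roughly nominal rate", {
  m <- expand_to_microstates(build_canonical_model("WT"), 5)
  cover <- 0
  n_rep <- 15
  for (r in seq_len(n_rep)) {
    ts <- simulate_dtrajs(m, 30, 4000, seed = 300 + r)
    b <- bootstrap_msm(ts, lag = 1, n_macro = 5, n_boot = 40,
                       seed = 400 + r, level = 0.8,
                       timestep = m$timestep_ns * 1e-6)
    map <- match_macrostates(b, m$micro_to_macro)
    k <- match(1, map)
    if (0.41 >= b$ci$pop[k, 1] && 0.41 <= b$ci$pop[k, 2]) cover <- cover + 1
  }
  # nominal 80%; allow generous binomial slack at n = 15
  expect_gte(cover, 7)
})
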