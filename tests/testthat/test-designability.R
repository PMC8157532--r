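# Hydrogen-bond detection, per-state profiles, designability ranking and
# structural metrics.

toy_frame <- function(o_pos) {
  # donor residue 1 (N with explicit H pointing at +x), acceptor residue 5
  data.frame(
    elety = c("N", "H", "CA", "O"),
    resno = c(1L, 1L, 1L, 5L),
    x = c(0, 1.0, -0.7, o_pos),
    y = c(0, 0, 1.2, 0),
    z = c(0, 0, 0, 0))
}

test_that("geometric criterion classifies ideal and distant pairs", {
  path <- tempfile(fileext = ".pdb")
  write_toy_pdb(list(toy_frame(2.9), toy_frame(5.0)), path)
  tab <- detect_hbonds(path, max_da = 3.5, min_dha = 120)
  f0 <- tab[tab$frame == 0 & tab$donor_res == 1 & tab$acceptor_res == 5, ]
  expect_equal(nrow(f0), 1)
  expect_true(f0$present)           # 2.9 A, 180 degrees
  expect_equal(f0$angle, 180, tolerance = 1e-6)
  f1 <- tab[tab$frame == 1 & tab$donor_res == 1 & tab$acceptor_res == 5, ]
  expect_true(nrow(f1) == 0 || !any(f1$present))  # 5.0 A fails the cutoff
})

test_that("detection equals brute-force evaluation and is rigid-body invariant", {
  set.seed(51)
  n_res <- 4
  at <- do.call(rbind, lapply(seq_len(n_res), function(r) {
    base <- c(runif(1, 0, 8), runif(1, 0, 8), runif(1, 0, 8))
    data.frame(elety = c("N", "H", "O"), resno = r,
               x = base[1] + c(0, 1.0, 2.2) + rnorm(3, 0, 0.2),
               y = base[2] + c(0, 0, 0.4), z = base[3] + c(0, 0, 0))
  }))
  path <- tempfile(fileext = ".pdb")
  write_toy_pdb(list(at), path)
  tab <- detect_hbonds(path, max_da = 3.5, min_dha = 120)

  # brute force over all donor(N-H) x acceptor(O) pairs
  xyz <- as.matrix(at[, c("x", "y", "z")])
  brute <- 0L
  for (d in which(at$elety == "N")) for (a in which(at$elety == "O")) {
    if (at$resno[d] == at$resno[a]) next
    h <- which(at$elety == "H" & at$resno == at$resno[d])
    dist <- sqrt(sum((xyz[a, ] - xyz[d, ])^2))
    v1 <- xyz[d, ] - xyz[h, ]; v2 <- xyz[a, ] - xyz[h, ]
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    if (dist <= 3.5 && ang >= 120) brute <- brute + 1L
  }
  expect_equal(sum(tab$present), brute)

  # rigid-body transform: rotate + translate all coordinates
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3)
  at2 <- at
  xyz2 <- t(R %*% t(xyz)) + matrix(c(3, -2, 7), nrow(at), 3, byrow = TRUE)
  at2$x <- xyz2[, 1]; at2$y <- xyz2[, 2]; at2$z <- xyz2[, 3]
  path2 <- tempfile(fileext = ".pdb")
  write_toy_pdb(list(at2), path2)
  tab2 <- detect_hbonds(path2, max_da = 3.5, min_dha = 120)
  expect_equal(tab2$present, tab$present)
  expect_equal(tab2$distance, tab$distance, tolerance = 1e-2)
})

test_that("per-state count distributions are normalised and match the binomial law", {
  m <- build_canonical_model("WT")
  ts <- simulate_dtrajs(m, 4, 4000, seed = 53)
  obs <- emit_observables(ts, m, seed = 54)
  long <- hbond_long(obs$hbonds)
  prof <- state_hbond_profiles(long, residue = 66)
  for (p in prof) expect_equal(sum(p), 1, tolerance = 1e-12)

  # in 70s-closed states the three residue-66 bonds are independent
  # Bernoulli(0.9, 0.85, 0.8); compare against the exact count law
  p_true <- c(0.9, 0.85, 0.8)
  pmf <- rep(0, 4)
  for (b1 in 0:1) for (b2 in 0:1) for (b3 in 0:1) {
    k <- b1 + b2 + b3
    pmf[k + 1] <- pmf[k + 1] +
      prod(ifelse(c(b1, b2, b3) == 1, p_true, 1 - p_true))
  }
  emp <- prof[["o100_c70"]]
  emp_full <- rep(0, 4)
  emp_full[as.integer(names(emp)) + 1] <- emp
  expect_lt(max(abs(cumsum(emp_full) - cumsum(pmf))), 0.04)
})

test_that("designability ranking finds the planted residue and is antisymmetric", {
  m <- build_canonical_model("WT")
  ts <- simulate_dtrajs(m, 4, 3000, seed = 55)
  obs <- emit_observables(ts, m, seed = 56)
  long <- hbond_long(obs$hbonds)
  w <- setNames(m$pops, m$labels)
  rk <- designability_rank(long, weights = w)
  expect_equal(rk$residue[rk$rank == 1], 66)
  expect_lt(abs(rk$delta[rk$residue == 70]), 0.05)
  expect_equal(rk$delta, rk$mean_closed - rk$mean_open)
  expect_setequal(rk$rank, seq_len(nrow(rk)))

  # swapping the group labels flips the sign of every delta
  rk_sw <- designability_rank(long,
                              closed_states = c("intermediate", "o100_o70",
                                                "c100_o70"),
                              open_states = c("o100_c70", "c100_c70"),
                              weights = w)
  i <- match(rk$residue, rk_sw$residue)
  expect_equal(rk_sw$delta[i], -rk$delta, tolerance = 1e-12)

  expect_warning(designability_rank(long), "population")
})

test_that("structure metrics agree with a hand-rolled Kabsch solution", {
  set.seed(57)
  n <- 12
  ref <- matrix(rnorm(3 * n, sd = 3), n, 3)
  # rigidly transformed copies: RMSD 0 after superposition
  th <- 0.5
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3)
  frames <- t(vapply(1:5, function(i)
    as.vector(t(ref %*% R + matrix(i, n, 3))), numeric(3 * n)))
  sm <- structure_metrics(frames, as.vector(t(ref)))
  expect_lt(max(sm$rmsd), 1e-6)
  expect_lt(max(sm$rmsf), 1e-6)

  # noisy ensemble: per-frame RMSD equals the independent Kabsch oracle
  noisy <- frames + matrix(rnorm(length(frames), sd = 0.4), nrow(frames))
  sm2 <- structure_metrics(noisy, as.vector(t(ref)))
  oracle <- vapply(1:5, function(i)
    kabsch_rmsd(ref, matrix(noisy[i, ], n, 3, byrow = TRUE)), numeric(1))
  expect_equal(sm2$rmsd, oracle, tolerance = 1e-6)

  expect_error(structure_metrics(frames[, 1:6], as.vector(t(ref))[1:6]),
               "3 atoms")
})
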