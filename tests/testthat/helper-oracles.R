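# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths.

# Adjusted Rand index between two label vectors.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# Largest strongly connected component by boolean reachability (matrix
# powers), brute force.
brute_largest_scc <- function(C) {
  A <- C > 0
  n <- nrow(A)
  R <- A | diag(TRUE, n)
  for (k in seq_len(n)) R <- R | (R %*% R) > 0
  mutual <- R & t(R)
  groups <- apply(mutual, 1, function(r) paste(which(r), collapse = ","))
  sizes <- table(groups)
  best <- names(sizes)[which.max(sizes)]
  sort(which(groups == best))
}

# Monte-Carlo mean first passage time on a discrete chain, using the
# package's low-level sampler only as an RNG-driven chain generator.
mc_mfpt <- function(P, pi, source, target, n_samples, max_steps, seed) {
  set.seed(seed)
  w <- pi[source] / sum(pi[source])
  hits <- numeric(0)
  batch <- 500
  cumP <- t(apply(P, 1, cumsum)); cumP[, ncol(cumP)] <- 1
  while (length(hits) < n_samples) {
    init <- sample(source, batch, replace = TRUE, prob = w)
    mat <- msmdesign:::simulate_chain_cpp(cumP, as.integer(init),
                                          as.integer(max_steps))
    for (k in seq_len(batch)) {
      idx <- which(mat[, k] %in% target)
      if (length(idx)) hits <- c(hits, idx[1] - 1L)
    }
  }
  hits <- hits[seq_len(n_samples)]
  c(mean = mean(hits), se = sd(hits) / sqrt(n_samples))
}

# Kabsch superposition: optimal RMSD between two coordinate sets
# (n_atoms x 3), hand-rolled via SVD.
kabsch_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  S <- svd(crossprod(Pc, Qc))
  d <- sign(det(S$v %*% t(S$u)))
  U <- S$v %*% diag(c(1, 1, d)) %*% t(S$u)
  sqrt(mean(rowSums((Qc - Pc %*% t(U))^2)))
}

# Rigid-rotor heteronuclear NOE from an independently coded spectral
# density (S2 = 1, no internal motion).
noe_rigid_oracle <- function(tau_c_ns, field_mhz) {
  gh <- 2.6752218744e8; gn <- -2.7126e7
  hbar <- 1.054571817e-34; mu0 <- 4 * pi * 1e-7
  r <- 1.02e-10; csa <- -160e-6
  tc <- tau_c_ns * 1e-9
  wH <- 2 * pi * field_mhz * 1e6
  wN <- wH * 0.1013
  J <- function(w) 0.4 * tc / (1 + (w * tc)^2)
  d <- (mu0 / (4 * pi)) * abs(gh * gn) * hbar / r^3
  c2 <- (wN * csa)^2 / 3
  R1 <- (d^2 / 4) * (J(wH - wN) + 3 * J(wN) + 6 * J(wH + wN)) + c2 * J(wN)
  sigma <- (d^2 / 4) * (6 * J(wH + wN) - J(wH - wN))
  1 + (-9.865) * sigma / R1  # documented gammaH/gammaN convention
}

# Write a multi-model PDB file from a list of per-model atom tables
# (columns: elety, resno, x, y, z; resid defaults to ALA).
write_toy_pdb <- function(models, path) {
  lines <- character(0)
  for (m in seq_along(models)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    at <- models[[m]]
    for (i in seq_len(nrow(at))) {
      el <- substr(gsub("[0-9]", "", at$elety[i]), 1, 1)
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        i, at$elety[i], "ALA", "A", at$resno[i], at$x[i], at$y[i], at$z[i],
        1.0, 0.0, el))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# Canonical WT model cached for reuse across tests (macro-level).
wt_macro_model <- local({
  model <- NULL
  function() {
    if (is.null(model)) model <<- build_canonical_model("WT")
    model
  }
})
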