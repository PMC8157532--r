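# Internal linear-algebra helpers for reversible Markov models.

# Stationary distribution of a row-stochastic matrix (dominant left
# eigenvector, normalised).
stationary_dist <- function(T) {
  e <- eigen(t(T))
  i <- which.max(Re(e$values))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

# Matrix exponential expm(Q * t) for a generator Q in detailed balance with
# pi, via symmetrisation: S = D^{1/2} Q D^{-1/2} is symmetric, so the
# eigendecomposition is exact and stable. Returns a row-stochastic matrix.
expm_db <- function(Q, pi, t = 1) {
  s <- sqrt(pi)
  S <- sweep(sweep(Q, 1, s, "*"), 2, s, "/")
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  M <- e$vectors %*% (exp(e$values * t) * t(e$vectors))
  P <- sweep(sweep(M, 1, s, "/"), 2, s, "*")
  P[P < 0 & P > -1e-12] <- 0
  P / rowSums(P)
}

# Mean first passage time (continuous time) from a set of source states to a
# set of target states under generator Q (rates per ms), weighted by the
# stationary distribution restricted to the source set. Returns ms.
mfpt_generator <- function(Q, pi, source, target) {
  n <- nrow(Q)
  stopifnot(length(intersect(source, target)) == 0)
  keep <- setdiff(seq_len(n), target)
  h <- numeric(n)
  h[keep] <- solve(Q[keep, keep, drop = FALSE], rep(-1, length(keep)))
  w <- pi[source] / sum(pi[source])
  sum(w * h[source])
}

# Detailed-balance check: max |pi_i T_ij - pi_j T_ji|
db_residual <- function(T, pi) {
  F <- pi * T
  max(abs(F - t(F)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
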