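# Reversible Markov state model estimation from discrete trajectories.

#' Count lagged transitions in discrete trajectories
#'
#' @param dtrajs list of integer state sequences (1-based), or a
#'   `trajectory_set`
#' @param lag lag time in steps (>= 1)
#' @param mode `"sliding"` counts every (t, t+lag) pair; `"strided"` counts
#'   non-overlapping pairs at t = 1, 1+lag, ...
#' @param n_states optional total number of states (defaults to the
#'   largest observed index)
#' @return object of class `count_matrix`: list with `counts` (square
#'   matrix), `lag`, `mode`, `n_frames_used`
#' @export
#' @examples
#' count_transitions(list(c(1, 2, 1, 2, 1)), lag = 1)$counts
count_transitions <- function(dtrajs, lag = 1, mode = c("sliding", "strided"),
                              n_states = NULL) {
  if (inherits(dtrajs, "trajectory_set")) dtrajs <- dtrajs$dtrajs
  mode <- match.arg(mode)
  stopifnot(lag >= 1)
  if (all(lengths(dtrajs) <= lag))
    stop("all trajectories are shorter than the lag time")
  n <- n_states %||% max(unlist(lapply(dtrajs, max)))
  C <- matrix(0, n, n)
  used <- 0L
  for (d in dtrajs) {
    L <- length(d)
    if (L <= lag) next
    if (mode == "sliding") {
      from <- d[seq_len(L - lag)]
      to <- d[seq_len(L - lag) + lag]
    } else {
      idx <- seq(1, L - lag, by = lag)
      from <- d[idx]
      to <- d[idx + lag]
    }
    tab <- tabulate((from - 1L) * n + to, nbins = n * n)
    C <- C + matrix(tab, n, n, byrow = TRUE)
    used <- used + length(from)
  }
  structure(list(counts = C, lag = as.integer(lag), mode = mode,
                 n_frames_used = used), class = "count_matrix")
}

#' Largest strongly connected set of states
#'
#' Maximal set of states mutually reachable through nonzero transition
#' counts; reversible estimation is restricted to this set.
#'
#' @param counts a `count_matrix` or a square count matrix
#' @return integer vector of state indices (sorted); largest component,
#'   ties broken by the component containing the lowest state index
#' @export
largest_connected_set <- function(counts) {
  C <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (length(C) == 0 || sum(C) == 0) stop("empty count matrix")
  g <- igraph::graph_from_adjacency_matrix(C > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    first_member <- vapply(best, function(b) min(which(comp$membership == b)), numeric(1))
    best <- best[which.min(first_member)]
  }
  sort(which(comp$membership == best))
}

#' Maximum-likelihood reversible transition matrix
#'
#' Estimates the transition matrix maximising the likelihood of the counts
#' under the detailed-balance constraint, by the standard self-consistent
#' fixed-point iteration on the symmetric flux matrix
#' x_ij <- (c_ij + c_ji) / (c_i/x_i + c_j/x_j).  Detailed balance holds
#' exactly at every iterate; convergence is declared when the stationary
#' distribution moves by less than `tol` (max norm).
#'
#' @param counts a `count_matrix` (restricted internally to its largest
#'   connected set) or a square matrix
#' @param tol convergence tolerance on the stationary distribution
#' @param max_iter maximum number of fixed-point iterations
#' @return object of class `msm_estimate`: list with `T` (row-stochastic),
#'   `pi`, `lag`, `active_set` (original state indices), `loglik`
#' @export
#' @examples
#' est <- estimate_reversible_T(count_transitions(list(c(1,2,1,2,1)), 1))
#' est$T
estimate_reversible_T <- function(counts, tol = 1e-10, max_iter = 1e5) {
  if (inherits(counts, "count_matrix")) {
    lag <- counts$lag
    C <- counts$counts
  } else {
    lag <- 1L
    C <- counts
  }
  active <- largest_connected_set(C)
  C <- C[active, active, drop = FALSE]
  ci <- rowSums(C)
  Csym <- C + t(C)
  X <- reversible_mle_cpp(Csym, ci, tol, as.integer(max_iter))
  if (!attr(X, "converged"))
    stop("reversible MLE did not converge after ", max_iter,
         " iterations (last residual ", signif(attr(X, "residual"), 3), ")")
  X <- matrix(as.numeric(X), nrow(X), ncol(X))
  Tm <- X / rowSums(X)
  pi <- rowSums(X)
  loglik <- sum(C[C > 0] * log(Tm[C > 0]))
  structure(list(T = Tm, pi = pi, lag = lag, active_set = active,
                 loglik = loglik), class = "msm_estimate")
}

#' @export
print.msm_estimate <- function(x, ...) {
  cat("Reversible MSM:", length(x$pi), "states, lag", x$lag,
      "steps, loglik", signif(x$loglik, 8), "\n")
  invisible(x)
}

#' Implied timescales and Chapman-Kolmogorov validation
#'
#' Computes the slowest `n_macro - 1` implied timescales
#' t_k(tau) = -tau / log(lambda_k(tau)) across a set of lag times, and the
#' Chapman-Kolmogorov deviation max |T_macro(tau)^k - T_macro(k tau)| of
#' the macrostate-aggregated transition matrices.  Flat timescales across
#' lags and small CK deviations indicate Markovian dynamics at the chosen
#' resolution.
#'
#' @param dtrajs list of integer trajectories or `trajectory_set`
#' @param lags lag times in steps (>= 2 values for the timescale profile)
#' @param n_macro number of slow processes + 1
#' @param ck_steps powers k at which to evaluate the CK deviation
#' @return list with `its` (matrix: lag x timescale, in steps) and `ck`
#'   (data.frame: lag, k, deviation)
#' @export
validate_msm <- function(dtrajs, lags, n_macro, ck_steps = 2:5) {
  if (inherits(dtrajs, "trajectory_set")) dtrajs <- dtrajs$dtrajs
  stopifnot(length(lags) >= 2)
  n_states <- max(unlist(lapply(dtrajs, max)))
  ests <- lapply(lags, function(l)
    estimate_reversible_T(count_transitions(dtrajs, l, n_states = n_states)))

  its <- t(vapply(seq_along(lags), function(k) {
    implied_timescales(ests[[k]], n_macro - 1)
  }, numeric(n_macro - 1)))
  rownames(its) <- lags

  ref <- pcca_lump(ests[[1]], n_macro)
  agg <- function(est) {
    memb <- ref$membership[est$active_set]
    A <- matrix(0, n_macro, n_macro)
    w <- est$pi
    for (I in seq_len(n_macro)) {
      sel <- memb == I
      if (!any(sel)) next
      wi <- w[sel] / sum(w[sel])
      for (J in seq_len(n_macro))
        A[I, J] <- sum(wi * rowSums(est$T[sel, memb == J, drop = FALSE]))
    }
    A
  }
  base_lag <- lags[1]
  A1 <- agg(ests[[1]])
  ck <- do.call(rbind, lapply(ck_steps, function(k) {
    if (!(base_lag * k) %in% lags) {
      estk <- estimate_reversible_T(
        count_transitions(dtrajs, base_lag * k, n_states = n_states))
    } else {
      estk <- ests[[match(base_lag * k, lags)]]
    }
    Ak <- agg(estk)
    Apow <- A1
    for (i in seq_len(k - 1)) Apow <- Apow %*% A1
    data.frame(lag = base_lag, k = k, deviation = max(abs(Apow - Ak)))
  }))
  list(its = its, ck = ck)
}

# Slowest m nontrivial implied timescales (in lag steps) of an estimate.
implied_timescales <- function(est, m) {
  pi <- est$pi
  s <- sqrt(pi)
  A <- sweep(sweep(est$T, 1, s, "*"), 2, s, "/")
  A <- (A + t(A)) / 2
  ev <- sort(eigen(A, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  lam <- ev[2:(m + 1)]
  lam[lam <= 0] <- NA_real_
  -est$lag / log(lam)
}

#' Cluster feature-space frames into microstates
#'
#' k-means with k-means++-style seeding (greedy D^2 sampling under a fixed
#' seed), preserving trajectory boundaries in the returned labels.
#'
#' @param features data.frame with a `traj` column and numeric feature
#'   columns (as produced by [emit_observables()]), or a numeric matrix
#'   (treated as one trajectory)
#' @param k number of clusters
#' @param seed integer RNG seed
#' @param feature_cols optional character vector naming feature columns
#' @return list of integer label vectors (1..k), one per trajectory;
#'   attribute `centers` holds the cluster centres
#' @export
cluster_features <- function(features, k, seed, feature_cols = NULL) {
  if (is.matrix(features)) {
    X <- features
    traj_id <- rep(1L, nrow(X))
  } else {
    feature_cols <- feature_cols %||%
      setdiff(names(features)[vapply(features, is.numeric, logical(1))],
              c("traj", "frame"))
    X <- as.matrix(features[, feature_cols, drop = FALSE])
    traj_id <- features$traj %||% rep(1L, nrow(X))
  }
  stopifnot(k >= 1, all(is.finite(X)))
  if (k > nrow(X)) stop("k exceeds the number of frames")
  set.seed(as.integer(seed))
  centers <- .kmeanspp_init(X, k)
  if (k == 1) {
    labels <- rep(1L, nrow(X))
  } else {
    km <- kmeans(X, centers = centers, iter.max = 100)
    labels <- km$cluster
    centers <- km$centers
  }
  out <- split(labels, traj_id)
  out <- lapply(out, as.integer)
  attr(out, "centers") <- centers
  out
}

.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums(sweep(X, 2, X[idx[1], ], "-")^2)
    for (j in 2:k) {
      p <- d2 / sum(d2)
      idx[j] <- sample.int(n, 1, prob = p)
      d2 <- pmin(d2, rowSums(sweep(X, 2, X[idx[j], ], "-")^2))
    }
  }
  X[idx, , drop = FALSE]
}
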