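# Spectral coarse-graining, mean first passage times, and trajectory
# bootstrap for estimated MSMs.

#' Lump microstates into macrostates by spectral (PCCA-style) analysis
#'
#' Computes fuzzy memberships from the `n_macro` dominant right
#' eigenvectors of the reversible transition matrix (simplex-vertex
#' construction: the rows of the eigenvector matrix are mapped onto a
#' simplex whose vertices are found by greedy orthogonal deflation, and
#' memberships are the barycentric coordinates).  Crisp assignment is by
#' argmax, ties broken towards the lowest macrostate index.
#'
#' @param msm an `msm_estimate`
#' @param n_macro number of macrostates (2..n_states)
#' @param timestep time per lag step in arbitrary units (used for the MFPT
#'   matrix; default 1 step)
#' @param mfpt_matrix compute the pairwise macrostate MFPT matrix (set
#'   FALSE to skip the n_macro^2 linear solves)
#' @return object of class `macrostate_model`: list with `membership`
#'   (crisp micro -> macro), `fuzzy` (membership matrix), `macro_pi`,
#'   `mfpt_matrix` (units of `timestep`), `active_set`, `lag`, `ci` (NULL
#'   until [bootstrap_msm()])
#' @export
#' @examples
#' m <- expand_to_microstates(build_canonical_model("WT"), 4)
#' ts <- simulate_dtrajs(m, 20, 3000, seed = 7)
#' est <- estimate_reversible_T(count_transitions(ts, lag = 1))
#' pcca_lump(est, 5)$macro_pi
pcca_lump <- function(msm, n_macro, timestep = 1, mfpt_matrix = TRUE) {
  stopifnot(inherits(msm, "msm_estimate"))
  n <- length(msm$pi)
  stopifnot(n_macro >= 2, n_macro <= n)
  if (n_macro == n) {
    memb <- seq_len(n)
    fuzzy <- diag(n)
  } else {
    pi <- msm$pi
    s <- sqrt(pi)
    A <- sweep(sweep(msm$T, 1, s, "*"), 2, s, "/")
    A <- (A + t(A)) / 2
    e <- eigen(A, symmetric = TRUE)
    ord <- order(e$values, decreasing = TRUE)
    vals <- e$values[ord]
    gap_num <- vals[n_macro] - vals[n_macro + 1]
    if (gap_num < 1e-12 * max(1, abs(vals[n_macro])))
      stop("eigenvalue degeneracy at the requested cut; ",
           "try a different n_macro")
    Psi <- sweep(e$vectors[, ord[seq_len(n_macro)], drop = FALSE], 1, s, "/")
    Psi[, 1] <- 1
    fuzzy <- .pcca_memberships(Psi)
    memb <- max.col(fuzzy, ties.method = "first")
    # ensure every macrostate is populated
    if (length(unique(memb)) < n_macro)
      stop("degenerate lumping: a macrostate received no microstates; ",
           "try a different n_macro")
  }
  macro_pi <- as.numeric(tapply(msm$pi, memb, sum))
  M <- NULL
  if (mfpt_matrix) {
    M <- matrix(0, n_macro, n_macro)
    for (I in seq_len(n_macro)) for (J in seq_len(n_macro)) if (I != J)
      M[I, J] <- mfpt(msm, which(memb == I), which(memb == J),
                      timestep = timestep)
  }
  structure(list(membership = memb, fuzzy = fuzzy, macro_pi = macro_pi,
                 mfpt_matrix = M, active_set = msm$active_set,
                 lag = msm$lag, timestep = timestep, ci = NULL),
            class = "macrostate_model")
}

# Inner simplex algorithm: pick n_macro rows of Psi as simplex vertices by
# greedy orthogonal deflation, then invert to barycentric coordinates.
.pcca_memberships <- function(Psi) {
  m <- ncol(Psi)
  idx <- integer(m)
  idx[1] <- which.max(rowSums(Psi^2))
  for (j in seq_len(m - 1)) {
    Vsel <- Psi[idx[seq_len(j)], , drop = FALSE]
    Qb <- qr.Q(qr(t(Vsel)))
    R <- Psi - Psi %*% Qb %*% t(Qb)
    idx[j + 1] <- which.max(rowSums(R^2))
  }
  V <- Psi[idx, , drop = FALSE]
  Psi %*% solve(V)
}

#' Mean first passage time between state sets of an estimated MSM
#'
#' Solves the discrete first-passage linear system: hitting times h of the
#' target set satisfy h = lag*timestep + T h off the target, h = 0 on it.
#' The returned value averages h over the source set weighted by the
#' stationary distribution restricted to the source.
#'
#' @param msm an `msm_estimate`
#' @param source,target disjoint non-empty sets of state indices (within
#'   the active set, 1-based positions in `msm$T`)
#' @param timestep physical time per lag step
#' @return MFPT in units of `timestep`
#' @export
#' @examples
#' est <- structure(list(T = matrix(c(.9, .1, .1, .9), 2, byrow = TRUE),
#'                       pi = c(.5, .5), lag = 1L, active_set = 1:2),
#'                  class = "msm_estimate")
#' mfpt(est, 1, 2)  # 10
mfpt <- function(msm, source, target, timestep = 1) {
  Tm <- msm$T
  n <- nrow(Tm)
  source <- unique(as.integer(source))
  target <- unique(as.integer(target))
  stopifnot(length(source) > 0, length(target) > 0,
            length(intersect(source, target)) == 0,
            all(c(source, target) >= 1), all(c(source, target) <= n))
  keep <- setdiff(seq_len(n), target)
  A <- diag(length(keep)) - Tm[keep, keep, drop = FALSE]
  h <- tryCatch(solve(A, rep(msm$lag * timestep, length(keep))),
                error = function(e) stop("target set unreachable from some states"))
  hfull <- numeric(n)
  hfull[keep] <- h
  w <- msm$pi[source] / sum(msm$pi[source])
  sum(w * hfull[source])
}

#' Match estimated macrostates to reference groups
#'
#' Maps each estimated macrostate to the reference macrostate with which
#' it shares the largest stationary-weighted microstate overlap (greedy
#' one-to-one assignment).
#'
#' @param macro a `macrostate_model`
#' @param truth integer reference assignment micro -> macro (full state
#'   space; subsetted by the model's active set)
#' @param pi optional weights per active microstate (defaults to uniform)
#' @return integer vector: for each estimated macrostate index, the
#'   matched reference macrostate
#' @export
match_macrostates <- function(macro, truth, pi = NULL) {
  est <- macro$membership
  ref <- truth[macro$active_set]
  w <- pi %||% rep(1, length(est))
  ks <- sort(unique(est))
  rs <- sort(unique(ref))
  O <- matrix(0, length(ks), length(rs), dimnames = list(ks, rs))
  for (a in seq_along(ks)) for (b in seq_along(rs))
    O[a, b] <- sum(w[est == ks[a] & ref == rs[b]])
  out <- integer(length(ks))
  Ow <- O
  for (step in seq_along(ks)) {
    hit <- arrayInd(which.max(Ow), dim(Ow))
    out[hit[1]] <- rs[hit[2]]
    Ow[hit[1], ] <- -Inf
    Ow[, hit[2]] <- -Inf
  }
  out
}

#' Bootstrap uncertainties for macrostate populations and MFPTs
#'
#' Resamples whole trajectories with replacement, re-estimates the MSM and
#' the lumping on each replicate, matches replicate macrostates to the
#' point estimate by stationary-weighted overlap, and returns percentile
#' intervals.  Replicates that lose connectivity over the point-estimate
#' active set are dropped (an error is raised if more than half drop).
#'
#' @param dtrajs list of integer trajectories or a `trajectory_set`
#' @param lag lag time in steps
#' @param n_macro number of macrostates
#' @param n_boot number of bootstrap replicates
#' @param level confidence level (default 0.95)
#' @param seed integer RNG seed
#' @param timestep physical time per step
#' @return a `macrostate_model` (point estimate) whose `ci` field holds
#'   `level`, `n_used`, `pop` (matrix: macro x lower/upper) and `mfpt`
#'   (arrays of lower/upper MFPT bounds)
#' @export
bootstrap_msm <- function(dtrajs, lag, n_macro, n_boot = 200, level = 0.95,
                          seed = 1, timestep = 1) {
  if (inherits(dtrajs, "trajectory_set")) {
    if (timestep == 1) timestep <- dtrajs$timestep_ns
    dtrajs <- dtrajs$dtrajs
  }
  n_states <- max(unlist(lapply(dtrajs, max)))
  per_traj <- lapply(dtrajs, function(d)
    count_transitions(list(d), lag, n_states = n_states)$counts)
  total <- Reduce(`+`, per_traj)
  cm <- structure(list(counts = total, lag = as.integer(lag),
                       mode = "sliding", n_frames_used = NA_integer_),
                  class = "count_matrix")
  point_est <- estimate_reversible_T(cm)
  point <- pcca_lump(point_est, n_macro, timestep = timestep)

  n_traj <- length(dtrajs)
  set.seed(as.integer(seed))
  pops <- matrix(NA_real_, n_boot, n_macro)
  mfpts <- array(NA_real_, c(n_boot, n_macro, n_macro))
  dropped <- 0L
  for (b in seq_len(n_boot)) {
    pick <- sample.int(n_traj, n_traj, replace = TRUE)
    Cb <- Reduce(`+`, per_traj[pick])
    cb <- structure(list(counts = Cb, lag = as.integer(lag),
                         mode = "sliding", n_frames_used = NA_integer_),
                    class = "count_matrix")
    res <- tryCatch({
      estb <- estimate_reversible_T(cb)
      if (!identical(estb$active_set, point_est$active_set))
        stop("connectivity lost")
      lumpb <- pcca_lump(estb, n_macro, timestep = timestep)
      map <- match_macrostates(lumpb, point$membership, pi = estb$pi)
      list(map = map, lump = lumpb)
    }, error = function(e) NULL)
    if (is.null(res)) { dropped <- dropped + 1L; next }
    ord <- match(seq_len(n_macro), res$map)  # replicate index of reference k
    pops[b, ] <- res$lump$macro_pi[ord]
    mfpts[b, , ] <- res$lump$mfpt_matrix[ord, ord]
  }
  if (dropped > n_boot / 2)
    stop("more than half of the bootstrap replicates lost connectivity (",
         dropped, "/", n_boot, ")")
  a <- (1 - level) / 2
  q <- function(v) quantile(v, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  pop_ci <- t(apply(pops, 2, q))
  colnames(pop_ci) <- c("lower", "upper")
  mfpt_lo <- apply(mfpts, c(2, 3), function(v) q(v)[1])
  mfpt_hi <- apply(mfpts, c(2, 3), function(v) q(v)[2])
  point$ci <- list(level = level, n_used = n_boot - dropped,
                   n_dropped = dropped, pop = pop_ci,
                   mfpt = list(lower = mfpt_lo, upper = mfpt_hi),
                   pop_samples = pops)
  point
}

#' @export
print.macrostate_model <- function(x, ...) {
  cat("Macrostate model:", length(x$macro_pi), "states (lag", x$lag, ")\n")
  cat("  populations:", paste(sprintf("%.3f", x$macro_pi), collapse = " "), "\n")
  if (!is.null(x$ci))
    cat("  bootstrap", x$ci$level, "CI from", x$ci$n_used, "replicates\n")
  invisible(x)
}
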