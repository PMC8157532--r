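# Seeded simulation of discrete trajectories and state-conditioned
# observables from a kinetic model.

#' Simulate discrete microstate trajectories
#'
#' Draws `n_traj` independent realisations of the model's microstate
#' Markov chain, each `n_steps` long, with initial states sampled from the
#' stationary distribution.  Models without a microstate expansion are
#' simulated at the macrostate level (identity expansion).
#'
#' @param model a `kinetic_model`
#' @param n_traj number of trajectories
#' @param n_steps frames per trajectory (>= 2)
#' @param seed integer RNG seed; identical seeds give identical output
#' @return an object of class `trajectory_set`: list with `dtrajs` (list of
#'   integer vectors, 1-based microstate indices), `timestep_ns`, `seed`,
#'   `model_ref`, `micro_to_macro`
#' @export
#' @examples
#' m <- expand_to_microstates(build_canonical_model("WT"), 5)
#' ts <- simulate_dtrajs(m, n_traj = 3, n_steps = 100, seed = 1)
#' lengths(ts$dtrajs)
simulate_dtrajs <- function(model, n_traj, n_steps, seed) {
  stopifnot(inherits(model, "kinetic_model"), n_traj >= 1, n_steps >= 2)
  if (is.null(model$micro_T))
    model <- expand_to_microstates(model, 1, intra_rate_scale = 100)
  P <- model$micro_T
  if (any(!is.finite(P)) || max(abs(rowSums(P) - 1)) > 1e-8)
    stop("micro_T is not row-stochastic")
  cumP <- t(apply(P, 1, cumsum))
  cumP[, ncol(cumP)] <- 1
  set.seed(as.integer(seed))
  init <- sample.int(nrow(P), n_traj, replace = TRUE, prob = model$micro_pi)
  mat <- simulate_chain_cpp(cumP, as.integer(init), as.integer(n_steps))
  structure(list(
    dtrajs = lapply(seq_len(n_traj), function(k) mat[, k]),
    timestep_ns = model$timestep_ns,
    seed = as.integer(seed),
    model_ref = model$variant,
    micro_to_macro = model$micro_to_macro
  ), class = "trajectory_set")
}

#' Emit state-conditioned observables along trajectories
#'
#' For every frame, draws a feature vector from the occupied microstate's
#' Gaussian emission (mean/spread inherited from its macrostate) and
#' hydrogen-bond indicators as independent Bernoulli draws with the
#' occupied macrostate's per-pair probabilities.  Per-state chemical-shift
#' tables are copied from the model.
#'
#' @param traj a `trajectory_set` from [simulate_dtrajs()]
#' @param model the generating `kinetic_model`
#' @param seed integer RNG seed
#' @return list with `features` (data.frame: traj, frame, state label +
#'   feature columns), `hbonds` (data.frame: traj, frame, state label +
#'   one 0/1 column per bond pair), `shifts` (per-state list of shift
#'   tables), `seed`
#' @export
emit_observables <- function(traj, model, seed) {
  stopifnot(inherits(traj, "trajectory_set"), inherits(model, "kinetic_model"))
  if (is.null(model$micro_to_macro))
    model <- expand_to_microstates(model, 1, intra_rate_scale = 100)
  micro <- unlist(traj$dtrajs, use.names = FALSE)
  if (max(micro) > length(model$micro_to_macro))
    stop("trajectory visits microstates outside the model's range")
  macro <- model$micro_to_macro[micro]
  n_frames <- length(micro)
  traj_id <- rep(seq_along(traj$dtrajs), lengths(traj$dtrajs))
  frame_id <- unlist(lapply(lengths(traj$dtrajs), seq_len), use.names = FALSE) - 1L

  specs <- model$macrostates
  if (any(vapply(specs, function(s) is.null(s$feature_mean), logical(1))))
    stop("missing feature emission parameters for a state")

  set.seed(as.integer(seed))
  dims <- names(specs[[1]]$feature_mean)
  mu <- t(vapply(specs, function(s) s$feature_mean, numeric(length(dims))))
  sdv <- vapply(specs, function(s) s$feature_spread, numeric(1))
  feat <- mu[macro, , drop = FALSE] +
    matrix(rnorm(n_frames * length(dims)), n_frames) * sdv[macro]
  colnames(feat) <- dims
  features <- data.frame(traj = traj_id, frame = frame_id,
                         state = model$labels[macro], feat,
                         check.names = FALSE)

  hbonds <- NULL
  if (!is.null(specs[[1]]$hbond_prob)) {
    pairs <- specs[[1]]$hbond_prob[, c("residue", "partner")]
    pm <- vapply(specs, function(s) {
      if (is.null(s$hbond_prob)) stop("missing H-bond probabilities for state ", s$label)
      s$hbond_prob$p
    }, numeric(nrow(pairs)))
    hb <- matrix(0L, n_frames, nrow(pairs))
    for (b in seq_len(nrow(pairs)))
      hb[, b] <- rbinom(n_frames, 1L, pm[b, macro])
    colnames(hb) <- paste0("hb_", pairs$residue, "_", pairs$partner)
    hbonds <- data.frame(traj = traj_id, frame = frame_id,
                         state = model$labels[macro], hb, check.names = FALSE)
  }

  shifts <- lapply(specs, function(s) s$shifts)
  names(shifts) <- model$labels
  list(features = features, hbonds = hbonds, shifts = shifts,
       seed = as.integer(seed))
}

#' Convert an emitted hydrogen-bond frame table to long bond records
#'
#' @param hbonds the wide `hbonds` data.frame from [emit_observables()]
#' @return data.frame with columns `frame`, `residue`, `partner`,
#'   `present`, `state`
#' @export
hbond_long <- function(hbonds) {
  cols <- grep("^hb_", names(hbonds), value = TRUE)
  parts <- do.call(rbind, strsplit(sub("^hb_", "", cols), "_"))
  out <- do.call(rbind, lapply(seq_along(cols), function(k) {
    data.frame(frame = seq_len(nrow(hbonds)) - 1L,
               residue = as.integer(parts[k, 1]),
               partner = as.integer(parts[k, 2]),
               present = as.integer(hbonds[[cols[k]]]),
               state = hbonds$state)
  }))
  rownames(out) <- NULL
  out
}
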