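# Ground-truth kinetic landscapes for a two-loop exchanging protein.
#
# The canonical models describe five macrostates distinguished by the
# open/closed status of two surface loops ("70s", residues 65-77, and
# "100s", residues 100-110).  Opening/closing of the 70s loop proceeds via
# an intermediate and is about an order of magnitude slower than the 100s
# loop; a point mutation at the designable residue (D66A) inverts the 70s
# populations and accelerates the 70s kinetics roughly 12-fold.

.canonical_labels <- c("o100_c70", "c100_c70", "intermediate",
                       "o100_o70", "c100_o70")
.canonical_loop70  <- c("closed", "closed", "intermediate", "open", "open")
.canonical_loop100 <- c("open", "closed", "open", "open", "closed")

.canonical_pops <- list(
  WT   = c(o100_c70 = 0.41, c100_c70 = 0.29, intermediate = 0.05,
           o100_o70 = 0.13, c100_o70 = 0.12),
  D66A = c(o100_c70 = 0.15, c100_c70 = 0.10, intermediate = 0.40,
           o100_o70 = 0.18, c100_o70 = 0.17),
  H70A = c(o100_c70 = 0.41, c100_c70 = 0.29, intermediate = 0.05,
           o100_o70 = 0.13, c100_o70 = 0.12)
)

# Adjacency of the macrostate network: the two loops flip independently and
# the 70s loop passes through the intermediate (no direct closed<->open
# 70s transition).  Edge class "loop100" flips the 100s loop; "loop70"
# connects the closed/open groups to the intermediate.
.canonical_edges <- data.frame(
  i = c(1L, 4L, 1L, 2L, 3L, 3L),
  j = c(2L, 5L, 3L, 3L, 4L, 5L),
  class = c("loop100", "loop100", "loop70", "loop70", "loop70", "loop70")
)

# 2-D emission feature space: degree of 70s and 100s loop opening.
.canonical_feature_means <- rbind(
  o100_c70     = c(open70 = 0.0, open100 = 1.0),
  c100_c70     = c(open70 = 0.0, open100 = 0.0),
  intermediate = c(open70 = 0.5, open100 = 1.0),
  o100_o70     = c(open70 = 1.0, open100 = 1.0),
  c100_o70     = c(open70 = 1.0, open100 = 0.0)
)
.canonical_feature_spread <- 0.08

# Hydrogen-bond probabilities per (residue, loop partner) pair in the
# 70s-closed vs 70s-open groups.  Residue 66 carries the designable
# signature (many bonds in closed, few in open); residue 70 is the
# negative control (indistinguishable groups).
.canonical_hbond_pairs <- data.frame(
  residue  = c(66L, 66L, 66L, 70L, 70L, 68L, 73L, 82L),
  partner  = c(71L, 72L, 73L, 72L, 74L, 72L, 75L, 74L),
  p_closed = c(0.90, 0.85, 0.80, 0.50, 0.50, 0.60, 0.50, 0.40),
  p_open   = c(0.10, 0.10, 0.08, 0.50, 0.50, 0.40, 0.30, 0.34)
)

# Per-residue amide shifts (1H, 15N ppm) for the 70s-closed and 70s-open
# groups; the intermediate shares the open-group shifts.  Loop residues
# (65-77) separate between the groups, others do not.
.canonical_shifts <- data.frame(
  residue  = c(55L, 66L, 67L, 68L, 70L, 71L, 72L, 73L, 74L, 76L, 101L, 105L, 121L),
  dH_closed = c(7.60, 8.30, 8.10, 7.95, 8.50, 8.77, 8.05, 7.70, 8.40, 8.90, 8.00, 8.64, 7.85),
  dN_closed = c(117.0, 118.5, 120.0, 115.2, 119.0, 122.4, 108.9, 112.0, 109.5, 121.0, 123.0, 126.0, 113.5),
  dH_open   = c(7.60, 8.05, 8.18, 7.80, 8.47, 8.60, 8.22, 7.82, 8.25, 8.84, 8.00, 8.62, 7.85),
  dN_open   = c(117.0, 121.7, 118.6, 117.4, 119.3, 119.6, 111.9, 114.0, 106.8, 122.2, 123.0, 126.1, 113.5)
)

#' Macrostate specification
#'
#' Bundles the identity and emission parameters of one conformational
#' macrostate: loop status flags, equilibrium population, number of
#' microstates it expands to, Gaussian feature emissions, per-pair
#' hydrogen-bond probabilities and per-residue amide chemical shifts.
#'
#' @param label short state name
#' @param loop70,loop100 one of `"closed"`, `"open"`, `"intermediate"`
#' @param population equilibrium fraction in `[0, 1]`
#' @param n_micro number of microstates the state expands to
#' @param feature_mean named numeric vector, mean in feature space
#' @param feature_spread per-dimension standard deviation
#' @param hbond_prob data.frame with columns `residue`, `partner`, `p`
#' @param shifts data.frame with columns `residue`, `dH_ppm`, `dN_ppm`
#' @return an object of class `macrostate_spec`
#' @export
macrostate_spec <- function(label, loop70, loop100, population,
                            n_micro = 1L,
                            feature_mean = c(open70 = 0, open100 = 0),
                            feature_spread = 0.1,
                            hbond_prob = NULL,
                            shifts = NULL) {
  loop70 <- match.arg(loop70, c("closed", "open", "intermediate"))
  loop100 <- match.arg(loop100, c("closed", "open", "intermediate"))
  stopifnot(population >= 0, population <= 1, n_micro >= 1)
  if (!is.null(hbond_prob))
    stopifnot(all(hbond_prob$p >= 0 & hbond_prob$p <= 1))
  structure(list(label = label, loop70 = loop70, loop100 = loop100,
                 population = population, n_micro = as.integer(n_micro),
                 feature_mean = feature_mean,
                 feature_spread = feature_spread,
                 hbond_prob = hbond_prob, shifts = shifts),
            class = "macrostate_spec")
}

#' Build a canonical five-macrostate kinetic model
#'
#' Constructs the ground-truth landscape for one variant.  Populations are
#' fixed model constants: the WT ground state (100s-open/70s-closed) holds
#' 41% and the 70s-closed:open balance is 70:30; D66A inverts this to
#' 25:75 with the intermediate promoted to a 40% ground state; H70A equals
#' WT.  Off-diagonal rates are k_ij = c_ij * pi_j with symmetric c_ij
#' (detailed balance by construction), restricted to the loop-flip network
#' in which the 70s transition passes through the intermediate.  The
#' couplings are calibrated so that the WT 70s closed-to-open MFPT exceeds
#' the 100s open-to-closed MFPT by `ratio_70_100`, the 100s MFPT is 0.5 ms,
#' and the D66A 70s MFPT is `mutant_speedup`-fold shorter than WT.
#'
#' @param variant `"WT"`, `"D66A"` or `"H70A"`
#' @param timestep_ns trajectory sampling interval in ns
#' @param ratio_70_100 target ratio of 70s to 100s loop MFPTs (WT)
#' @param mutant_speedup fold-acceleration of the D66A 70s kinetics
#' @return an object of class `kinetic_model` with fields `variant`,
#'   `labels`, `loop70`, `loop100`, `pops`, `Q` (macrostate generator,
#'   rates per ms), `timestep_ns`, `macrostates`, and (after
#'   [expand_to_microstates()]) `micro_T`, `micro_pi`, `micro_to_macro`
#' @export
#' @examples
#' m <- build_canonical_model("WT")
#' m$pops
build_canonical_model <- function(variant = c("WT", "D66A", "H70A"),
                                  timestep_ns = 1000,
                                  ratio_70_100 = 11.5,
                                  mutant_speedup = 12) {
  if (length(variant) == 1 && !variant %in% c("WT", "D66A", "H70A"))
    stop("unknown variant: ", variant)
  variant <- match.arg(variant)
  pops <- .canonical_pops[[variant]]

  Q <- .calibrated_generator(pops, ratio_70_100)
  # absolute scale: WT/H70A anchored at a 0.5 ms 100s-loop MFPT
  # (millisecond-regime kinetics); D66A anchored 12-fold faster on the
  # 70s closed->open transition than WT.
  wtQ <- .calibrated_generator(.canonical_pops$WT, ratio_70_100)
  wt_m100 <- .macro_mfpt(wtQ, .canonical_pops$WT, "m100")
  wtQ <- wtQ * (wt_m100 / 0.5)
  if (variant %in% c("WT", "H70A")) {
    Q <- Q * (.macro_mfpt(Q, pops, "m100") / 0.5)
  } else {
    wt_m70 <- .macro_mfpt(wtQ, .canonical_pops$WT, "m70")
    Q <- Q * (.macro_mfpt(Q, pops, "m70") / (wt_m70 / mutant_speedup))
  }
  dimnames(Q) <- list(.canonical_labels, .canonical_labels)

  macrostates <- lapply(seq_along(.canonical_labels), function(k) {
    grp <- if (.canonical_loop70[k] == "closed") "closed" else "open"
    hb <- .canonical_hbond_pairs
    hb$p <- if (.canonical_loop70[k] == "intermediate")
      (hb$p_closed + hb$p_open) / 2
    else if (grp == "closed") hb$p_closed else hb$p_open
    sh <- data.frame(residue = .canonical_shifts$residue,
                     dH_ppm = if (grp == "closed") .canonical_shifts$dH_closed
                              else .canonical_shifts$dH_open,
                     dN_ppm = if (grp == "closed") .canonical_shifts$dN_closed
                              else .canonical_shifts$dN_open)
    macrostate_spec(label = .canonical_labels[k],
                    loop70 = .canonical_loop70[k],
                    loop100 = .canonical_loop100[k],
                    population = pops[[k]],
                    feature_mean = .canonical_feature_means[k, ],
                    feature_spread = .canonical_feature_spread,
                    hbond_prob = hb[, c("residue", "partner", "p")],
                    shifts = sh)
  })

  model <- structure(list(
    variant = variant,
    labels = .canonical_labels,
    loop70 = .canonical_loop70,
    loop100 = .canonical_loop100,
    pops = pops,
    Q = Q,
    timestep_ns = timestep_ns,
    macrostates = macrostates,
    micro_T = NULL, micro_pi = NULL, micro_to_macro = NULL,
    seed_policy = "one seeded RNG stream per generating call"
  ), class = "kinetic_model")
  validate_kinetic_model(model)
  model
}

# Generator with unit 100s coupling and the 70s/intermediate coupling
# solved (monotone 1-D root find) so that MFPT(70s)/MFPT(100s) = ratio.
.calibrated_generator <- function(pops, ratio) {
  build_Q <- function(x) {
    Q <- matrix(0, 5, 5)
    for (r in seq_len(nrow(.canonical_edges))) {
      i <- .canonical_edges$i[r]; j <- .canonical_edges$j[r]
      c_ij <- if (.canonical_edges$class[r] == "loop100") 1 else x
      Q[i, j] <- c_ij * pops[j]
      Q[j, i] <- c_ij * pops[i]
    }
    diag(Q) <- -rowSums(Q)
    Q
  }
  f <- function(lx) {
    Q <- build_Q(exp(lx))
    .macro_mfpt(Q, pops, "m70") / .macro_mfpt(Q, pops, "m100") - ratio
  }
  lx <- uniroot(f, c(log(1e-5), log(1e4)), tol = 1e-12)$root
  build_Q(exp(lx))
}

# The two reference MFPTs (ms): 70s closed group -> open group, and 100s
# open states -> 100s closed states.
.macro_mfpt <- function(Q, pops, which = c("m70", "m100")) {
  which <- match.arg(which)
  if (which == "m70")
    mfpt_generator(Q, pops, source = c(1, 2), target = c(4, 5))
  else
    mfpt_generator(Q, pops, source = c(1, 4), target = c(2, 5))
}

#' Validate the invariants of a kinetic model
#'
#' Checks population normalisation, generator row sums, detailed balance,
#' and (when a microstate expansion is present) stochasticity of the
#' microstate transition matrix and agreement of its aggregated stationary
#' distribution with the macrostate populations.
#'
#' @param model a `kinetic_model`
#' @return the model, invisibly; errors on violation
#' @export
validate_kinetic_model <- function(model) {
  stopifnot(inherits(model, "kinetic_model"))
  if (abs(sum(model$pops) - 1) > 1e-9)
    stop("macrostate populations must sum to 1")
  Q <- model$Q
  if (any(Q[row(Q) != col(Q)] < 0)) stop("negative off-diagonal rate")
  if (max(abs(rowSums(Q))) > 1e-9) stop("generator rows must sum to 0")
  if (db_residual(expm_db(Q, model$pops, 1e-3), model$pops) > 1e-10)
    stop("macrostate rates violate detailed balance")
  if (!is.null(model$micro_T)) {
    if (max(abs(rowSums(model$micro_T) - 1)) > 1e-12)
      stop("micro_T rows must sum to 1")
    pi_micro <- model$micro_pi
    agg <- tapply(pi_micro, model$micro_to_macro, sum)
    if (max(abs(agg - model$pops)) > 1e-6)
      stop("aggregated microstate stationary distribution != macrostate populations")
    if (db_residual(model$micro_T, pi_micro) > 1e-10)
      stop("micro_T violates detailed balance")
  }
  invisible(model)
}

#' Expand a macrostate model to a microstate transition matrix
#'
#' Each macrostate is split into `n_micro_per_macro` equally populated
#' microstates.  Microstates within a macrostate exchange on a complete
#' graph at `intra_rate_scale` times the fastest inter-macrostate rate,
#' and each inter-macrostate rate is spread uniformly over the microstate
#' pairs so that the expansion is exactly lumpable: the aggregated process
#' reproduces the macrostate kinetics and the slowest implied timescales
#' exactly.  The one-step transition matrix is the exponential of this
#' microstate generator over one sampling interval.
#'
#' @param model a `kinetic_model`
#' @param n_micro_per_macro microstates per macrostate
#' @param intra_rate_scale intra/inter rate separation (must be >= 50)
#' @return the model with `micro_T`, `micro_pi`, `micro_to_macro` set
#' @export
#' @examples
#' m <- expand_to_microstates(build_canonical_model("WT"), 20)
#' nrow(m$micro_T)  # 100
expand_to_microstates <- function(model, n_micro_per_macro = 20,
                                  intra_rate_scale = 100) {
  stopifnot(inherits(model, "kinetic_model"), n_micro_per_macro >= 1)
  n <- as.integer(n_micro_per_macro)
  Q <- model$Q
  k_max <- max(Q[row(Q) != col(Q)])
  if (intra_rate_scale < 50)
    stop("intra-macrostate exchange must be at least 50x the fastest ",
         "inter-macrostate rate (", signif(k_max, 4), " per ms); got scale ",
         intra_rate_scale)
  n_macro <- length(model$pops)
  N <- n_macro * n
  micro_to_macro <- rep(seq_len(n_macro), each = n)
  pi_micro <- model$pops[micro_to_macro] / n
  r_intra <- intra_rate_scale * k_max

  Qm <- matrix(0, N, N)
  for (i in seq_len(n_macro)) {
    idx <- which(micro_to_macro == i)
    if (n > 1) {
      Qm[idx, idx] <- r_intra / (n - 1)
    }
    for (j in seq_len(n_macro)) {
      if (i == j || Q[i, j] == 0) next
      jdx <- which(micro_to_macro == j)
      Qm[idx, jdx] <- Q[i, j] / n
    }
  }
  diag(Qm) <- 0
  diag(Qm) <- -rowSums(Qm)

  dt_ms <- model$timestep_ns * 1e-6
  micro_T <- expm_db(Qm, pi_micro, dt_ms)

  model$micro_T <- micro_T
  model$micro_pi <- pi_micro
  model$micro_to_macro <- micro_to_macro
  model$micro_Q <- Qm
  for (k in seq_len(n_macro)) model$macrostates[[k]]$n_micro <- n
  validate_kinetic_model(model)
  model
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("Kinetic model:", x$variant, "-", length(x$pops), "macrostates")
  if (!is.null(x$micro_T)) cat(",", nrow(x$micro_T), "microstates")
  cat("\n  populations:",
      paste(sprintf("%s=%.3f", x$labels, x$pops), collapse = " "), "\n")
  m70 <- .macro_mfpt(x$Q, x$pops, "m70")
  m100 <- .macro_mfpt(x$Q, x$pops, "m100")
  cat(sprintf("  MFPT 70s closed->open %.3f ms; 100s open->closed %.3f ms\n",
              m70, m100))
  invisible(x)
}

#' Ground-truth macrostate MFPT matrix of a kinetic model
#'
#' Pairwise set-to-set mean first passage times between macrostates from
#' the continuous-time generator (linear solve), in ms.
#'
#' @param model a `kinetic_model`
#' @return square matrix of MFPTs (ms) with zero diagonal
#' @export
model_mfpt_matrix <- function(model) {
  n <- length(model$pops)
  M <- matrix(0, n, n, dimnames = list(model$labels, model$labels))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    M[i, j] <- mfpt_generator(model$Q, model$pops, i, j)
  M
}
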