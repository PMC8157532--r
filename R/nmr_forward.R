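# Forward prediction of NMR observables from kinetic ensembles:
# population-averaged shifts, chemical shift perturbations, mapping of a
# macrostate model onto a two-state NMR exchange model, exchange
# broadening, and model-free heteronuclear NOE.

#' Population-weighted ensemble average of per-state chemical shifts
#'
#' Fast-exchange averaging: per residue and nucleus, the arithmetic mean
#' of the per-state shifts weighted by state populations.  Residues
#' missing from any state are omitted with a warning.
#'
#' @param populations numeric vector summing to 1, aligned with `shifts`
#' @param shifts list of per-state shift tables (data.frames with columns
#'   `residue`, `dH_ppm`, `dN_ppm`)
#' @return shift table data.frame (`residue`, `dH_ppm`, `dN_ppm`)
#' @export
#' @examples
#' a <- data.frame(residue = 1, dH_ppm = 8.0, dN_ppm = 120)
#' b <- data.frame(residue = 1, dH_ppm = 8.2, dN_ppm = 122)
#' ensemble_average_shifts(c(0.5, 0.5), list(a, b))
ensemble_average_shifts <- function(populations, shifts) {
  stopifnot(length(populations) == length(shifts),
            abs(sum(populations) - 1) < 1e-6)
  common <- Reduce(intersect, lapply(shifts, function(s) s$residue))
  all_res <- unique(unlist(lapply(shifts, function(s) s$residue)))
  if (length(common) < length(all_res))
    warning("residues missing from some states omitted: ",
            paste(setdiff(all_res, common), collapse = ", "))
  if (length(common) == 0) stop("no residue present in every state")
  dH <- rep(0, length(common))
  dN <- rep(0, length(common))
  for (k in seq_along(shifts)) {
    s <- shifts[[k]]
    i <- match(common, s$residue)
    dH <- dH + populations[k] * s$dH_ppm[i]
    dN <- dN + populations[k] * s$dN_ppm[i]
  }
  data.frame(residue = common, dH_ppm = dH, dN_ppm = dN)
}

#' Combined chemical shift perturbation between two shift tables
#'
#' Per shared residue, sqrt(ddH^2 + (alpha * ddN)^2) with the usual 15N
#' down-weighting alpha = 0.14.
#'
#' @param a,b shift tables (`residue`, `dH_ppm`, `dN_ppm`)
#' @param alpha 15N weighting factor
#' @return data.frame with columns `residue`, `csp_ppm`; attribute
#'   `alpha`
#' @export
#' @examples
#' a <- data.frame(residue = 1, dH_ppm = 8.0, dN_ppm = 120)
#' b <- data.frame(residue = 1, dH_ppm = 8.1, dN_ppm = 121)
#' csp(a, b)$csp_ppm  # sqrt(0.1^2 + 0.14^2)
csp <- function(a, b, alpha = 0.14) {
  shared <- intersect(a$residue, b$residue)
  if (length(shared) == 0) stop("no shared residues between shift tables")
  ia <- match(shared, a$residue)
  ib <- match(shared, b$residue)
  v <- sqrt((a$dH_ppm[ia] - b$dH_ppm[ib])^2 +
            (alpha * (a$dN_ppm[ia] - b$dN_ppm[ib]))^2)
  structure(data.frame(residue = shared, csp_ppm = v), alpha = alpha)
}

#' Map a macrostate model onto a two-state NMR exchange model
#'
#' Groups macrostates by 70s-loop status (closed vs open, the
#' intermediate joining the open group), aggregates populations, derives
#' kex = 1/MFPT(A to B) + 1/MFPT(B to A) from the group-to-group mean
#' first passage times, and computes per-residue shift differences
#' between the within-group population-weighted average shifts
#' (fast intra-group exchange assumed).
#'
#' @param model a `kinetic_model` (ground truth), or a
#'   `macrostate_model` together with `labels70` and `shifts`
#' @param field_mhz 1H field for the rad/s conversion
#' @param labels70 per-macrostate 70s status (required for estimated
#'   models): vector of `"closed"`/`"open"`/`"intermediate"`
#' @param shifts per-state list of shift tables (required for estimated
#'   models)
#' @param mfpt_ms optional 2-vector c(A to B, B to A) in ms, overriding
#'   MFPTs derived from the model
#' @return object of class `exchange_mapping`: list with `pA`, `pB`,
#'   `kex_s`, `group` (per macrostate), `dw` (data.frame: residue,
#'   dw_ppm, dw_rad), `field_mhz`
#' @export
map_to_exchange_model <- function(model, field_mhz = 600, labels70 = NULL,
                                  shifts = NULL, mfpt_ms = NULL) {
  if (inherits(model, "kinetic_model")) {
    labels70 <- model$loop70
    shifts <- lapply(model$macrostates, function(s) s$shifts)
    pops <- model$pops
    A <- which(labels70 == "closed")
    B <- which(labels70 != "closed")
    if (length(A) == 0 || length(B) == 0) stop("a group has no macrostates")
    if (is.null(mfpt_ms))
      mfpt_ms <- c(mfpt_generator(model$Q, pops, A, B),
                   mfpt_generator(model$Q, pops, B, A))
  } else if (inherits(model, "macrostate_model")) {
    if (is.null(labels70) || is.null(shifts))
      stop("labels70 and shifts are required for an estimated model")
    pops <- model$macro_pi
    A <- which(labels70 == "closed")
    B <- which(labels70 != "closed")
    if (length(A) == 0 || length(B) == 0) stop("a group has no macrostates")
    if (is.null(mfpt_ms))
      stop("mfpt_ms is required for an estimated model")
  } else stop("model must be a kinetic_model or macrostate_model")
  pA <- sum(pops[A])
  pB <- sum(pops[B])
  if (pA <= 0 || pB <= 0) stop("zero-population group in the 70s split")
  tot <- pA + pB
  pA <- pA / tot; pB <- pB / tot
  kex_s <- 1000 / mfpt_ms[1] + 1000 / mfpt_ms[2]

  avg <- function(idx) ensemble_average_shifts(pops[idx] / sum(pops[idx]),
                                               shifts[idx])
  sa <- avg(A); sb <- avg(B)
  shared <- intersect(sa$residue, sb$residue)
  ia <- match(shared, sa$residue); ib <- match(shared, sb$residue)
  dw_ppm <- sb$dN_ppm[ib] - sa$dN_ppm[ia]
  dw <- data.frame(residue = shared, dw_ppm = dw_ppm,
                   dw_rad = ppm_to_rad(dw_ppm, field_mhz))
  structure(list(pA = pA, pB = pB, kex_s = kex_s,
                 group = ifelse(seq_along(pops) %in% A, "A", "B"),
                 dw = dw, field_mhz = field_mhz),
            class = "exchange_mapping")
}

#' Forward-predicted exchange broadening from an exchange mapping
#'
#' Rex per residue as R2eff(nu_min) - R2eff(nu_max) under the two-state
#' dispersion forward model, with the fast-exchange closed form
#' pA pB dw^2 / kex reported alongside.
#'
#' @param mapping an `exchange_mapping`
#' @param nu_min,nu_max lowest/highest CPMG frequencies (Hz)
#' @param r20 intrinsic R2 assumed for the forward curves (1/s)
#' @param method forward model passed to [r2eff_two_state_cpmg()]
#' @return data.frame: `residue`, `rex_s`, `rex_fast_s`
#' @export
rex_forward <- function(mapping, nu_min = 25, nu_max = 1000, r20 = 15,
                        method = "numerical") {
  stopifnot(inherits(mapping, "exchange_mapping"))
  pB <- min(mapping$pA, mapping$pB)
  kex <- mapping$kex_s
  out <- lapply(seq_len(nrow(mapping$dw)), function(i) {
    dw <- abs(mapping$dw$dw_rad[i])
    if (dw == 0) return(data.frame(residue = mapping$dw$residue[i],
                                   rex_s = 0, rex_fast_s = 0))
    r2 <- r2eff_two_state_cpmg(pB, kex, dw, r20, c(nu_min, nu_max),
                               method = method)
    data.frame(residue = mapping$dw$residue[i],
               rex_s = r2[1] - r2[2],
               rex_fast_s = (1 - pB) * pB * dw^2 / kex)
  })
  do.call(rbind, out)
}

#' Steady-state heteronuclear 15N-{1H} NOE from model-free parameters
#'
#' Uses the two-timescale model-free spectral density
#' J(w) = (2/5)(S^2 tau_c / (1 + (w tau_c)^2) + (1 - S^2) tau /
#' (1 + (w tau)^2)) with 1/tau = 1/tau_c + 1/tau_e, dipolar (N-H, 1.02 A)
#' and 15N CSA (-160 ppm) contributions:
#' NOE = 1 + (gammaH/gammaN) sigma_NH / R1.
#'
#' @param S2 order parameter in `[0, 1]`
#' @param tau_c global rotational correlation time (ns)
#' @param tau_e internal correlation time (ps); must be shorter than
#'   `tau_c`
#' @param field_mhz 1H field (MHz)
#' @return list with `noe`, `r1_s`, `sigma_s`
#' @export
#' @examples
#' noe_from_modelfree(0.85, tau_c = 8, tau_e = 50, field_mhz = 600)$noe
noe_from_modelfree <- function(S2, tau_c, tau_e = 50, field_mhz = 600) {
  if (S2 < 0 || S2 > 1) stop("S2 must be in [0, 1]")
  if (tau_c <= 0 || tau_e < 0) stop("correlation times must be positive")
  tc <- tau_c * 1e-9
  te <- tau_e * 1e-12
  if (te >= tc) stop("tau_e must be shorter than tau_c")
  k <- .nmr_const
  wH <- 2 * pi * field_mhz * 1e6
  wN <- wH * k$n15_larmor_frac
  tau <- 1 / (1 / tc + ifelse(te > 0, 1 / te, 0))
  J <- function(w) {
    free <- if (S2 < 1 && te > 0) (1 - S2) * tau / (1 + (w * tau)^2) else 0
    (2 / 5) * (S2 * tc / (1 + (w * tc)^2) + free)
  }
  d <- (k$mu0 / (4 * pi)) * abs(k$gamma_h * k$gamma_n) * k$hbar / k$r_nh^3
  c2 <- (wN * k$csa_n)^2 / 3
  R1 <- (d^2 / 4) * (J(wH - wN) + 3 * J(wN) + 6 * J(wH + wN)) + c2 * J(wN)
  sigma <- (d^2 / 4) * (6 * J(wH + wN) - J(wH - wN))
  list(noe = 1 + k$gamma_ratio_hn * sigma / R1, r1_s = R1, sigma_s = sigma)
}
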