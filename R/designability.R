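# Hydrogen-bond based designability scoring and basic structural metrics.
#
# The design idea: residues that make many hydrogen bonds to a loop in
# one conformational state and few in the other are leverage points --
# removing such an interaction (e.g. an Asp -> Ala mutation) selectively
# destabilises the state that relied on it.

#' Detect hydrogen bonds in a multi-model coordinate ensemble
#'
#' Geometric criterion: a donor-acceptor pair is bonded when the
#' heavy-atom distance is at or below `max_da` Angstrom and the
#' donor-H...acceptor angle is at or above `min_dha` degrees (inclusive
#' bounds).  Donors are N/O atoms carrying a hydrogen; acceptors are O
#' (and sidechain N without H).  When a donor has no hydrogen in the
#' model, the H is placed geometrically 1.01 A from the donor along the
#' direction away from the centroid of its bonded heavy atoms, and the
#' bond is flagged `h_inferred`.
#'
#' @param pdb_file path to a multi-model PDB file, or a `bio3d` pdb
#'   object
#' @param max_da donor-acceptor distance cutoff (Angstrom)
#' @param min_dha D-H...A angle cutoff (degrees)
#' @param same_residue_exclude skip pairs within one residue (default
#'   TRUE)
#' @return data.frame (class `hbond_table`): `frame` (0-based), `donor_res`,
#'   `donor_atom`, `acceptor_res`, `acceptor_atom`, `distance`, `angle`,
#'   `present`, `h_inferred`; one row per candidate pair per frame with
#'   distance at most `max_da` + 1.5 A (wider pairs are never bonded and
#'   are omitted for compactness)
#' @export
detect_hbonds <- function(pdb_file, max_da = 3.5, min_dha = 120,
                          same_residue_exclude = TRUE) {
  stopifnot(max_da > 0, min_dha > 0)
  pdb <- if (inherits(pdb_file, "pdb")) pdb_file else
    bio3d::read.pdb(pdb_file, multi = TRUE)
  at <- pdb$atom
  n_frames <- nrow(pdb$xyz)
  elem <- at$elety
  is_h <- grepl("^[0-9]*H", elem)
  heavy <- which(!is_h)
  rows <- list()
  skipped <- 0L
  for (fr in seq_len(n_frames)) {
    xyz <- matrix(pdb$xyz[fr, ], ncol = 3, byrow = TRUE)
    if (any(!is.finite(xyz[heavy, ]))) {
      warning("model ", fr, " has missing heavy-atom coordinates; skipped")
      skipped <- skipped + 1L
      next
    }
    tab <- .hbond_frame(at, xyz, max_da, min_dha, same_residue_exclude)
    if (nrow(tab)) {
      tab$frame <- fr - 1L
      rows[[length(rows) + 1]] <- tab
    }
  }
  if (skipped == n_frames) stop("all models were malformed")
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(), donor_res = integer(),
               donor_atom = character(), acceptor_res = integer(),
               acceptor_atom = character(), distance = numeric(),
               angle = numeric(), present = logical(),
               h_inferred = logical())
  out <- out[, c("frame", "donor_res", "donor_atom", "acceptor_res",
                 "acceptor_atom", "distance", "angle", "present",
                 "h_inferred")]
  class(out) <- c("hbond_table", "data.frame")
  attr(out, "criterion") <- c(max_da = max_da, min_dha = min_dha)
  attr(out, "n_frames") <- n_frames - skipped
  out
}

.hbond_frame <- function(at, xyz, max_da, min_dha, same_residue_exclude) {
  elem <- at$elety
  is_h <- grepl("^[0-9]*H", elem)
  first_char <- substr(gsub("^[0-9]+", "", elem), 1, 1)
  is_n <- first_char == "N" & !is_h
  is_o <- first_char == "O" & !is_h
  # attach hydrogens to the nearest heavy N/O within 1.25 A
  h_idx <- which(is_h)
  donor_of_h <- rep(NA_integer_, length(h_idx))
  cand <- which(is_n | is_o)
  for (k in seq_along(h_idx)) {
    same_res <- cand[at$resno[cand] == at$resno[h_idx[k]]]
    if (!length(same_res)) next
    d <- sqrt(colSums((t(xyz[same_res, , drop = FALSE]) - xyz[h_idx[k], ])^2))
    if (min(d) <= 1.25) donor_of_h[k] <- same_res[which.min(d)]
  }
  donors <- unique(stats::na.omit(donor_of_h))
  # N/O without attached H can still donate via an inferred hydrogen
  donors_noh <- setdiff(which(is_n), donors)
  acceptors <- which(is_o)
  res <- list()
  add_pair <- function(di, ai, hpos, h_inferred) {
    dvec <- xyz[ai, ] - xyz[di, ]
    dist <- sqrt(sum(dvec^2))
    if (dist > max_da + 1.5) return()
    v1 <- xyz[di, ] - hpos
    v2 <- xyz[ai, ] - hpos
    ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                               (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
    res[[length(res) + 1]] <<- data.frame(
      donor_res = at$resno[di], donor_atom = trimws(elem[di]),
      acceptor_res = at$resno[ai], acceptor_atom = trimws(elem[ai]),
      distance = dist, angle = ang,
      present = dist <= max_da & ang >= min_dha,
      h_inferred = h_inferred)
  }
  for (ai in acceptors) {
    for (k in seq_along(h_idx)) {
      di <- donor_of_h[k]
      if (is.na(di) || di == ai) next
      if (same_residue_exclude && at$resno[di] == at$resno[ai]) next
      add_pair(di, ai, xyz[h_idx[k], ], FALSE)
    }
    for (di in donors_noh) {
      if (di == ai) next
      if (same_residue_exclude && at$resno[di] == at$resno[ai]) next
      nb <- which(!is_h & at$resno == at$resno[di])
      d_nb <- sqrt(colSums((t(xyz[nb, , drop = FALSE]) - xyz[di, ])^2))
      nb <- nb[d_nb > 0 & d_nb <= 1.7]
      if (!length(nb)) next
      centroid <- colMeans(xyz[nb, , drop = FALSE])
      u <- xyz[di, ] - centroid
      u <- u / sqrt(sum(u^2))
      add_pair(di, ai, xyz[di, ] + 1.01 * u, TRUE)
    }
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(donor_res = integer(), donor_atom = character(),
               acceptor_res = integer(), acceptor_atom = character(),
               distance = numeric(), angle = numeric(),
               present = logical(), h_inferred = logical())
}

#' Per-state distributions of hydrogen-bond counts
#'
#' For each macrostate, the empirical distribution of the per-frame
#' number of bonds between `residue` and any member of `partners`.
#'
#' @param bonds long bond records: data.frame with columns `frame`,
#'   `residue`, `partner`, `present`, `state` (e.g. from [hbond_long()])
#' @param residue the residue whose bonds are counted
#' @param partners partner residues (default: 70s loop, residues 65-77)
#' @return named list (per state) of probability tables over counts;
#'   states without frames are omitted with a warning
#' @export
state_hbond_profiles <- function(bonds, residue, partners = 65:77) {
  if (is.null(bonds$state)) stop("state labels are required")
  sub <- bonds[bonds$residue == residue & bonds$partner %in% partners, ,
               drop = FALSE]
  states <- unique(bonds$state)
  out <- list()
  for (st in states) {
    frames <- unique(bonds$frame[bonds$state == st])
    if (!length(frames)) {
      warning("state ", st, " has no frames; omitted")
      next
    }
    ssub <- sub[sub$state == st, , drop = FALSE]
    counts <- tapply(ssub$present, factor(ssub$frame, levels = frames), sum)
    counts[is.na(counts)] <- 0
    tab <- table(factor(counts, levels = 0:max(counts)))
    out[[st]] <- as.numeric(tab) / sum(tab)
    names(out[[st]]) <- names(tab)
  }
  out
}

#' Rank residues by hydrogen-bond designability
#'
#' Designability of a residue is the difference between the expected
#' number of bonds it makes to the partner set in the 70s-closed state
#' group and in the 70s-open group, each a population-weighted
#' expectation over the group's states.  Residues are ranked by |delta|.
#'
#' @param bonds long bond records (`frame`, `residue`, `partner`,
#'   `present`, `state`)
#' @param closed_states,open_states state labels of the two groups
#' @param weights named state populations (missing -> unweighted means
#'   with a warning)
#' @param partners partner residue set (default 70s loop 65-77)
#' @return data.frame (sorted by rank): `residue`, `mean_closed`,
#'   `mean_open`, `delta`, `rank`
#' @export
designability_rank <- function(bonds,
                               closed_states = c("o100_c70", "c100_c70"),
                               open_states = c("intermediate", "o100_o70",
                                               "c100_o70"),
                               weights = NULL, partners = 65:77) {
  stopifnot(length(closed_states) > 0, length(open_states) > 0)
  if (is.null(weights)) {
    warning("no state populations supplied; using unweighted group means")
    weights <- setNames(rep(1, length(c(closed_states, open_states))),
                        c(closed_states, open_states))
  }
  residues <- sort(unique(bonds$residue))
  per_state_mean <- function(res, st) {
    sub <- bonds[bonds$residue == res & bonds$partner %in% partners &
                 bonds$state == st, , drop = FALSE]
    frames <- unique(bonds$frame[bonds$state == st])
    if (!length(frames)) return(NA_real_)
    sum(sub$present) / length(frames)
  }
  group_mean <- function(res, states) {
    m <- vapply(states, function(st) per_state_mean(res, st), numeric(1))
    w <- weights[states]
    w[is.na(w)] <- 0
    ok <- !is.na(m) & w > 0
    if (!any(ok)) return(NA_real_)
    sum(w[ok] * m[ok]) / sum(w[ok])
  }
  mc <- vapply(residues, function(r) group_mean(r, closed_states), numeric(1))
  mo <- vapply(residues, function(r) group_mean(r, open_states), numeric(1))
  out <- data.frame(residue = residues, mean_closed = mc, mean_open = mo,
                    delta = mc - mo)
  out <- out[order(-abs(out$delta)), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Per-residue RMSF and per-frame RMSD of a coordinate ensemble
#'
#' Frames are superposed onto the reference by least-squares (Kabsch)
#' rotation/translation on the selected atoms before computing metrics.
#' RMSF is about the ensemble mean structure; RMSD is per frame against
#' the reference.
#'
#' @param xyz numeric matrix, frames x (3 * n_atoms), e.g. `pdb$xyz`
#' @param ref numeric vector of reference coordinates (length 3 *
#'   n_atoms)
#' @return list with `rmsf` (per atom) and `rmsd` (per frame), Angstrom
#' @export
structure_metrics <- function(xyz, ref) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == length(ref), ncol(xyz) %% 3 == 0)
  n_atoms <- ncol(xyz) / 3
  if (n_atoms < 3) stop("superposition requires at least 3 atoms")
  fitted <- bio3d::fit.xyz(fixed = ref, mobile = xyz,
                           fixed.inds = seq_along(ref),
                           mobile.inds = seq_along(ref))
  rmsd <- sqrt(rowSums(sweep(fitted, 2, ref)^2) / n_atoms)
  mean_xyz <- colMeans(fitted)
  dev2 <- sweep(fitted, 2, mean_xyz)^2
  per_atom <- matrix(colMeans(dev2), ncol = 3, byrow = TRUE)
  list(rmsf = sqrt(rowSums(per_atom)), rmsd = rmsd)
}
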