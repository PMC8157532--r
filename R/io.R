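# Plain-text file interfaces: discrete trajectories (one state per line
# plus a JSON manifest), feature/H-bond/dispersion CSV dialects, kinetic
# model YAML, and JSON results.

#' Write a trajectory set to a directory
#'
#' One file per trajectory (`traj_0001.txt`, one integer state per line)
#' plus `manifest.json` with the timestep, model id and seed.
#'
#' @param traj a `trajectory_set`
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_dtrajs <- function(traj, dir) {
  stopifnot(inherits(traj, "trajectory_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("traj_%04d.txt", seq_along(traj$dtrajs))
  for (k in seq_along(traj$dtrajs))
    writeLines(as.character(traj$dtrajs[[k]]), file.path(dir, files[k]))
  manifest <- list(timestep_ns = traj$timestep_ns, seed = traj$seed,
                   model_ref = traj$model_ref, files = files,
                   micro_to_macro = traj$micro_to_macro)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a trajectory set written by [write_dtrajs()]
#'
#' @param dir directory containing trajectory files and `manifest.json`
#' @return a `trajectory_set`
#' @export
read_dtrajs <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("manifest.json not found in ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  for (f in c("timestep_ns", "seed", "files"))
    if (is.null(manifest[[f]])) stop("manifest.json: missing field '", f, "'")
  dtrajs <- lapply(manifest$files, function(f) {
    v <- readLines(file.path(dir, f))
    x <- suppressWarnings(as.integer(v))
    if (any(is.na(x)))
      stop("non-integer state in ", f, " at line ", which(is.na(x))[1])
    x
  })
  structure(list(dtrajs = dtrajs, timestep_ns = manifest$timestep_ns,
                 seed = manifest$seed, model_ref = manifest$model_ref,
                 micro_to_macro = manifest$micro_to_macro),
            class = "trajectory_set")
}

#' Write/read a dispersion dataset as CSV
#'
#' Columns: residue, field_mhz, experiment (cpmg|r1rho), nu_cpmg_hz,
#' omega1_hz, offset_hz, rate_s, error_s.  Numeric values are written at
#' full precision.
#'
#' @param data a `dispersion_dataset`
#' @param path CSV path
#' @return the path (write) / the dataset (read), metadata attributes
#'   `r1` and `t_relax` preserved via a JSON side-car comment line is NOT
#'   used; pass `r1` explicitly on read if needed
#' @export
write_dispersion_csv <- function(data, path) {
  cols <- c("residue", "field_mhz", "experiment", "nu_cpmg_hz",
            "omega1_hz", "offset_hz", "rate_s", "error_s")
  stopifnot(all(cols %in% names(data)))
  df <- as.data.frame(data)[, cols]
  for (c in setdiff(cols, "experiment"))
    df[[c]] <- format(df[[c]], digits = 17, trim = TRUE, scientific = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dispersion_csv
#' @param r1 longitudinal rate to attach (1/s)
#' @param t_relax CPMG constant-time delay to attach (s)
#' @export
read_dispersion_csv <- function(path, r1 = 1.5, t_relax = 0.04) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  cols <- c("residue", "field_mhz", "experiment", "nu_cpmg_hz",
            "omega1_hz", "offset_hz", "rate_s", "error_s")
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("dispersion CSV schema violation: missing column(s) ",
         paste(missing, collapse = ", "))
  if (!all(df$experiment %in% c("cpmg", "r1rho")))
    stop("dispersion CSV schema violation: experiment must be cpmg|r1rho (line ",
         which(!df$experiment %in% c("cpmg", "r1rho"))[1] + 1, ")")
  structure(df, class = c("dispersion_dataset", "data.frame"),
            r1 = r1, t_relax = t_relax)
}

#' Serialise a kinetic model to YAML and back
#'
#' Round-trips the variant, timestep, populations, macrostate generator
#' and per-state emission parameters.  The microstate expansion is
#' reconstructed on read when the expansion settings are recorded.
#'
#' @param model a `kinetic_model`
#' @param path YAML file path
#' @return the path, invisibly
#' @export
write_model_yaml <- function(model, path) {
  stopifnot(inherits(model, "kinetic_model"))
  obj <- list(
    variant = model$variant,
    timestep_ns = model$timestep_ns,
    labels = model$labels,
    loop70 = model$loop70,
    loop100 = model$loop100,
    pops = as.numeric(model$pops),
    Q = apply(unname(model$Q), 1, as.numeric, simplify = FALSE),
    seed_policy = model$seed_policy,
    macrostates = lapply(model$macrostates, function(s) list(
      label = s$label, loop70 = s$loop70, loop100 = s$loop100,
      population = as.numeric(s$population), n_micro = s$n_micro,
      feature_mean = as.list(s$feature_mean),
      feature_spread = s$feature_spread,
      hbond_prob = if (is.null(s$hbond_prob)) NULL else
        lapply(seq_len(nrow(s$hbond_prob)), function(i)
          list(residue = s$hbond_prob$residue[i],
               partner = s$hbond_prob$partner[i],
               p = s$hbond_prob$p[i])),
      shifts = if (is.null(s$shifts)) NULL else
        lapply(seq_len(nrow(s$shifts)), function(i)
          list(residue = s$shifts$residue[i],
               dH_ppm = s$shifts$dH_ppm[i],
               dN_ppm = s$shifts$dN_ppm[i])))),
    expansion = if (is.null(model$micro_T)) NULL else
      list(n_micro_per_macro = sum(model$micro_to_macro == 1),
           intra_rate_scale = attr(model, "intra_rate_scale") %||% 100)
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_model_yaml
#' @export
read_model_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  for (f in c("variant", "timestep_ns", "labels", "pops", "Q"))
    if (is.null(obj[[f]])) stop("model YAML: missing field '", f, "'")
  n <- length(obj$labels)
  Q <- t(vapply(obj$Q, as.numeric, numeric(n)))
  dimnames(Q) <- list(obj$labels, obj$labels)
  macrostates <- lapply(obj$macrostates, function(s) {
    hb <- if (is.null(s$hbond_prob)) NULL else
      do.call(rbind, lapply(s$hbond_prob, as.data.frame))
    sh <- if (is.null(s$shifts)) NULL else
      do.call(rbind, lapply(s$shifts, as.data.frame))
    macrostate_spec(s$label, s$loop70, s$loop100, s$population,
                    n_micro = s$n_micro,
                    feature_mean = unlist(s$feature_mean),
                    feature_spread = s$feature_spread,
                    hbond_prob = hb, shifts = sh)
  })
  model <- structure(list(
    variant = obj$variant, labels = obj$labels,
    loop70 = obj$loop70, loop100 = obj$loop100,
    pops = setNames(as.numeric(obj$pops), obj$labels), Q = Q,
    timestep_ns = obj$timestep_ns, macrostates = macrostates,
    micro_T = NULL, micro_pi = NULL, micro_to_macro = NULL,
    seed_policy = obj$seed_policy %||% ""), class = "kinetic_model")
  if (!is.null(obj$expansion))
    model <- expand_to_microstates(model, obj$expansion$n_micro_per_macro,
                                   obj$expansion$intra_rate_scale)
  validate_kinetic_model(model)
  model
}

#' Write an estimated macrostate model as JSON
#'
#' @param macro a `macrostate_model`
#' @param path JSON path
#' @return the path, invisibly
#' @export
write_macro_json <- function(macro, path) {
  obj <- list(membership = macro$membership,
              macro_pi = macro$macro_pi,
              mfpt_matrix = macro$mfpt_matrix,
              lag = macro$lag, timestep = macro$timestep,
              active_set = macro$active_set,
              ci = if (is.null(macro$ci)) NULL else
                macro$ci[c("level", "n_used", "pop")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a two-state fit as JSON plus a per-residue CSV table
#'
#' The CSV mirrors a supplementary-table layout: global kex and pB in
#' header comment lines, then one row per residue with |dw| in ppm.
#'
#' @param fit a `two_state_fit`
#' @param json_path,csv_path output paths (NULL to skip either)
#' @return invisibly, the paths written
#' @export
write_fit_results <- function(fit, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    obj <- list(kex_s = fit$kex, pB = fit$pB, dw_ppm = as.list(fit$dw_ppm),
                r20 = fit$r20, chi2 = fit$chi2,
                chi2_reduced = fit$chi2_reduced,
                n_params = fit$n_params, n_points = fit$n_points,
                ci = if (is.null(fit$ci)) NULL else
                  fit$ci[c("level", "kex", "pB")])
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    con <- file(csv_path, "w")
    writeLines(c(sprintf("# kex_s,%.10g", fit$kex),
                 sprintf("# pB,%.10g", fit$pB)), con)
    write.csv(data.frame(residue = names(fit$dw_ppm),
                         dw_ppm = as.numeric(fit$dw_ppm)),
              con, row.names = FALSE)
    close(con)
  }
  invisible(c(json_path, csv_path))
}
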