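# ---- run configuration -----------------------------------------------------

default_config <- function() {
  list(
    seed = 1L,
    temperature = 300,    # K
    pressure = 1,         # bar
    reparam = list(
      reference = "spce_hydration",   # packaged set or a CSV path
      water_model = "spce",
      method = "mean_ratio"
    ),
    fep = list(
      n_carbons = 1L,
      water_model = "spce",
      delta = 0.025,               # 40 windows
      replicates = 3L,
      n_solvent = 200L,
      density = 8,                 # nm^-3
      n_sweeps = 160L,
      rc_cross = 1.4,              # nm
      rc_solvent = 1.0,            # nm
      shift_cross = FALSE,
      npt = FALSE
    ),
    corrections = list(
      rdf_file = NULL,             # NULL -> generate from a toy run
      n_carbons = 6L,
      water_model = "spce",
      rc = 1.4,                    # nm
      n_within = NULL,             # NULL -> geometric count
      density = 8,                 # nm^-3 solvent density for the toy run
      prefactor = "half"
    )
  )
}

#' Load and validate a run configuration
#'
#' Configurations are nested lists (optionally read from YAML). Unknown keys
#' are rejected rather than ignored, so typos cannot silently fall back to
#' defaults. Defaults mirror the standard protocol: 40 windows
#' (`delta = 0.025`), solute-solvent cutoff 1.4 nm, solvent-solvent cutoff
#' 1.0 nm, 300 K, 1 bar, 3 replicates.
#'
#' @param config `NULL` (all defaults), a nested list, or a YAML file path.
#' @return The merged, validated configuration list.
#' @export
load_config <- function(config = NULL) {
  base <- default_config()
  if (is.null(config)) return(base)
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("`config` must be NULL, a list or a YAML path.")
  merge_checked(base, config, path = "config")
}

merge_checked <- function(base, user, path) {
  extra <- setdiff(names(user), names(base))
  if (length(extra) > 0) {
    abort(paste0("unknown ", path, " key(s): ",
                 paste(extra, collapse = ", "), "."))
  }
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]])) {
      merge_checked(base[[k]], user[[k]], paste0(path, "$", k))
    } else user[[k]]
  }
  base
}

config_hash <- function(config) rlang::hash(config)

out_path <- function(out_dir, name, overwrite) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- file.path(out_dir, name)
  if (file.exists(p) && !overwrite) {
    abort(paste0("`", p, "` exists; pass overwrite = TRUE to replace it."))
  }
  p
}

write_report_csv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# seed: ", config$seed, "  config_hash: ",
                    config_hash(config)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Reparameterization pipeline
#'
#' End-to-end driver: loads the hydration reference table (packaged set or
#' user CSV with the same header), runs [build_reparam_table()] for the
#' configured water model, and writes the per-alkane hydration report, the
#' updated-epsilon table and a fit-diagnostics log. All outputs carry the
#' seed and a configuration hash in a header comment and are never
#' overwritten without `overwrite = TRUE`.
#'
#' @param config See [load_config()].
#' @param out_dir Output directory.
#' @param overwrite Replace existing outputs?
#' @return The `reparam_report`, invisibly; files
#'   `hydration_table.csv`, `updated_epsilon.csv`, `fit_log.txt`.
#' @export
run_reparam <- function(config = NULL, out_dir = tempfile("reparam"),
                        overwrite = FALSE) {
  config <- load_config(config)
  rc <- config$reparam
  records <- if (file.exists(rc$reference %||% "")) {
    read_hydration_csv(rc$reference)
  } else {
    load_reference(rc$reference)
  }
  pairs <- cross_pairs(rc$water_model)
  rep <- build_reparam_table(records, pairs, method = rc$method)
  write_report_csv(rep$records, out_path(out_dir, "hydration_table.csv",
                                         overwrite), config)
  write_report_csv(rep$pairs, out_path(out_dir, "updated_epsilon.csv",
                                       overwrite), config)
  log_path <- out_path(out_dir, "fit_log.txt", overwrite)
  writeLines(c(
    paste0("# seed: ", config$seed, "  config_hash: ", config_hash(config)),
    paste0("method: ", rep$fit$method),
    paste0("scale s: ", format(rep$fit$s, digits = 8)),
    paste0("ratio sd: ", format(sd(rep$fit$ratios$ratio), digits = 4)),
    paste0("n alkanes: ", nrow(rep$fit$ratios))
  ), log_path)
  invisible(rep)
}

read_hydration_csv <- function(path) {
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE),
    error = function(e) abort(paste0("could not parse `", path, "`: ",
                                     conditionMessage(e)))
  )
  need <- setdiff(c("n_carbons", "dg_hyd_exp", "dg_cavity", "dh_att_model"),
                  names(df))
  if (length(need) > 0) {
    abort(paste0("`", path, "` is missing column(s): ",
                 paste(need, collapse = ", "),
                 " (header line 1 must name them)."))
  }
  df
}

#' Free-energy-perturbation pipeline on the toy system
#'
#' Runs the configured number of independent replicates of the toy Monte
#' Carlo coupling simulation in both directions, accumulates the estimator
#' per replicate, and writes a per-window table and a summary (forward and
#' reverse totals, replicate mean and standard deviation, closure error).
#' Deterministic under a fixed seed: replicate r uses seed
#' `seed + 1000 * r`.
#'
#' @inheritParams run_reparam
#' @return Invisibly, a list with `summary` (tibble) and `per_window`;
#'   files `fep_windows.tsv`, `fep_summary.csv`.
#' @export
run_fep <- function(config = NULL, out_dir = tempfile("fep"),
                    overwrite = FALSE) {
  config <- load_config(config)
  fc <- config$fep
  solute <- build_alkane_chain(fc$n_carbons)
  pairs <- cross_pairs(fc$water_model)
  schedule <- lambda_schedule(fc$delta)
  run_one <- function(r, direction) {
    spec <- sim_spec(n_solvent = fc$n_solvent, density = fc$density,
                     temperature = config$temperature,
                     seed = config$seed + 1000L * r,
                     n_sweeps = fc$n_sweeps, rc_cross = fc$rc_cross,
                     rc_solvent = fc$rc_solvent,
                     shift_cross = fc$shift_cross,
                     npt = fc$npt, pressure = config$pressure)
    run <- mc_run(spec, solute, pairs, schedule, direction)
    fep_accumulate(run$samples, config$temperature)
  }
  reps <- seq_len(fc$replicates)
  fwd <- purrr::map(reps, run_one, direction = "forward")
  rev <- purrr::map(reps, run_one, direction = "reverse")
  fwd_tot <- purrr::map_dbl(fwd, "total")
  rev_tot <- purrr::map_dbl(rev, "total")
  fs <- replicate_stats(fwd_tot)
  rs <- replicate_stats(rev_tot)
  summary <- tibble(
    direction = c("forward", "reverse"),
    mean = c(fs$mean, rs$mean), sd = c(fs$sd, rs$sd),
    n_replicates = fc$replicates,
    closure = fep_hysteresis(fwd[[1]], rev[[1]]))
  per_window <- dplyr::bind_rows(
    purrr::imap(fwd, ~ dplyr::mutate(tidy(.x), replicate = .y,
                                     direction = "forward")),
    purrr::imap(rev, ~ dplyr::mutate(tidy(.x), replicate = .y,
                                     direction = "reverse")))
  win_path <- out_path(out_dir, "fep_windows.tsv", overwrite)
  writeLines(paste0("# seed: ", config$seed, "  config_hash: ",
                    config_hash(config)), win_path)
  readr::write_tsv(per_window, win_path, append = TRUE, col_names = TRUE)
  write_report_csv(summary, out_path(out_dir, "fep_summary.csv", overwrite),
                   config)
  invisible(list(summary = summary, per_window = per_window,
                 forward = fwd, reverse = rev))
}

#' Shift/tail correction pipeline
#'
#' Computes the correction terms for one alkane: the mean-energy and
#' cutoff-shift integrals from an RDF (a supplied TSV or one measured on a
#' fresh toy run), the analytic shift approximation, and the long-range
#' tail - each under both the 2-pi and 4-pi prefactor conventions, emitted
#' side by side.
#'
#' @inheritParams run_reparam
#' @return Invisibly, the corrections tibble; file `corrections.csv`.
#' @export
run_corrections <- function(config = NULL, out_dir = tempfile("corr"),
                            overwrite = FALSE) {
  config <- load_config(config)
  cc <- config$corrections
  solute <- build_alkane_chain(cc$n_carbons)
  pairs <- cross_pairs(cc$water_model)
  # one effective cross pair for the chain: count-weighted site mean
  pp <- pairs_for_sites(solute$site, pairs)
  eff <- pair_par(mean(pp$epsilon), mean(pp$sigma))
  if (!is.null(cc$rdf_file)) {
    rdf <- read_rdf(cc$rdf_file)
    rho <- attr(rdf, "rho") %||% cc$density
  } else {
    spec <- sim_spec(seed = config$seed, density = cc$density,
                     temperature = config$temperature,
                     rc_cross = cc$rc, n_sweeps = 200)
    traj <- mc_sample_frames(spec, solute, pairs, lam = 1, n_frames = 100)
    rdf <- compute_rdf(traj)
    rho <- attr(rdf, "rho")
  }
  if (max(rdf$r) < cc$rc) {
    abort("RDF domain is shorter than the cutoff `rc`.")
  }
  n_sites <- nrow(solute)
  n_within <- cc$n_within %||% count_within_cutoff(solute, cc$rc)
  sig_eff <- effective_cross_sigma(solute, pairs)
  u_rc <- lj_energy(cc$rc, eff)
  one <- function(pref) {
    tibble(
      prefactor = pref,
      n_sites = n_sites, n_within = as.numeric(n_within),
      u_rc = u_rc,
      mean_energy = mean_energy_from_rdf(rdf, eff, n_sites, rho, cc$rc, pref),
      shift_rdf = shift_energy_from_rdf(rdf, u_rc, n_sites, rho, cc$rc, pref),
      shift_approx = shift_energy_approx(u_rc, n_sites, n_within, rho,
                                         cc$rc, sig_eff, pref),
      tail = tail_correction(n_sites, rho, eff, cc$rc, pref))
  }
  out <- dplyr::bind_rows(one("half"), one("full"))
  write_report_csv(out, out_path(out_dir, "corrections.csv", overwrite),
                   config)
  invisible(out)
}
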