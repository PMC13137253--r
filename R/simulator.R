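#' Rigid all-trans united-atom alkane geometry
#'
#' Builds the ideal all-trans zig-zag chain used as the rigid solute: C-C
#' bonds of 0.154 nm and a C-C-C angle of 114 degrees, lying in the xy
#' plane. Conformational sampling is deliberately absent; none of the
#' estimators under test depend on torsional states.
#'
#' @param n_carbons Number of carbons (>= 1).
#' @param bond C-C bond length, nm.
#' @param angle C-C-C angle, degrees.
#' @return Tibble with columns `site` (CH4/CH3/CH2 labels) and `x`, `y`, `z`
#'   in nm, centred at the origin.
#' @examples
#' build_alkane_chain(2) # two CH3 sites 0.154 nm apart
#' @export
build_alkane_chain <- function(n_carbons, bond = 0.154, angle = 114) {
  sites <- alkane_sites(n_carbons)
  th <- angle * pi / 180
  k <- seq_len(n_carbons) - 1L
  x <- k * bond * sin(th / 2)
  y <- (k %% 2) * bond * cos(th / 2)
  out <- tibble(site = sites$site,
                x = x - mean(x), y = y - mean(y), z = 0)
  out
}

#' Toy-simulation specification
#'
#' Collects every knob of the Metropolis Monte Carlo sampler: a neutral
#' Lennard-Jones solvent (a "water surrogate" with the diameter and well
#' depth of a water oxygen, no charges) around one rigid solute, NVT by
#' default with an optional NPT mode driven by logarithmic volume moves.
#' A quarter of each window's sweeps are discarded as burn-in by default,
#' mirroring the convention of averaging over the final three quarters of a
#' production run.
#'
#' @param n_solvent Number of solvent particles.
#' @param density Solvent number density in nm^-3 (fixes the cubic box).
#' @param temperature Temperature, K.
#' @param seed Master seed; every stochastic stage derives from it.
#' @param max_displacement Maximum single-particle move, nm.
#' @param n_sweeps Sweeps per lambda window (one sweep = `n_solvent` trial
#'   moves).
#' @param n_burnin Burn-in sweeps per window; default `round(n_sweeps / 4)`.
#' @param sample_every Record a sample every this many post-burn-in sweeps.
#' @param eps_solvent,sigma_solvent Solvent-solvent LJ parameters.
#' @param rc_cross,rc_solvent Spherical cutoffs (nm) for solute-solvent and
#'   solvent-solvent interactions; each must not exceed half the box edge.
#' @param shift_cross,shift_solvent Shift the respective potential to zero
#'   at its cutoff?
#' @param alpha,n_exp Soft-core constants for the cross interaction.
#' @param box Explicit cubic box edge in nm; by default derived from
#'   `n_solvent / density`. When both `box` and a positive `n_solvent` are
#'   given, the density is recomputed from them.
#' @param npt Enable volume moves (isothermal-isobaric sampling)?
#' @param pressure Pressure in bar (NPT only).
#' @param max_dlnV Maximum log-volume move (NPT only).
#' @param vol_every Attempt a volume move every this many sweeps (NPT only).
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(n_solvent = 200, density = 8, temperature = 300,
                     seed = 1L, max_displacement = 0.15,
                     n_sweeps = 160, n_burnin = NULL, sample_every = 2,
                     eps_solvent = 0.65, sigma_solvent = 0.3166,
                     rc_cross = 1.4, rc_solvent = 1.0,
                     shift_cross = FALSE, shift_solvent = FALSE,
                     alpha = 0.5, n_exp = 2L,
                     npt = FALSE, pressure = 1, max_dlnV = 0.02,
                     vol_every = 2L, box = NULL) {
  if (density <= 0) abort("`density` must be > 0 (nm^-3).")
  if (is.null(n_burnin)) n_burnin <- round(n_sweeps / 4)
  if (n_sweeps <= n_burnin || n_burnin < 0) {
    abort("`n_sweeps` must exceed `n_burnin` (>= 0).")
  }
  if (is.null(box)) {
    box <- if (n_solvent > 0) (n_solvent / density)^(1 / 3)
           else 2.02 * max(rc_cross, rc_solvent, 1) # empty box, size moot
  } else if (n_solvent > 0) {
    density <- n_solvent / box^3
  }
  if (2 * max(rc_cross, rc_solvent) > box * (1 + 1e-9)) {
    abort(paste0("cutoff exceeds half the box edge (box = ",
                 format(box, digits = 4),
                 " nm); reduce the cutoffs or enlarge the system."))
  }
  structure(list(
    n_solvent = as.integer(n_solvent), density = density, box = box,
    temperature = temperature, seed = as.integer(seed),
    max_displacement = max_displacement, n_sweeps = as.integer(n_sweeps),
    n_burnin = as.integer(n_burnin), sample_every = as.integer(sample_every),
    eps_solvent = eps_solvent, sigma_solvent = sigma_solvent,
    rc_cross = rc_cross, rc_solvent = rc_solvent,
    shift_cross = shift_cross, shift_solvent = shift_solvent,
    alpha = alpha, n_exp = as.integer(n_exp),
    npt = npt, pressure_red = pressure * bar_nm3_kJ_mol,
    max_dlnV = max_dlnV, vol_every = as.integer(vol_every)
  ), class = "sim_spec")
}

# map cross-pair rows to the solute's site labels
pairs_for_sites <- function(site, pairs) {
  pname <- sub(":O$", "", pairs$name %||% character())
  idx <- match(site, pname)
  if (anyNA(idx)) {
    abort(paste0("no cross pair for site(s): ",
                 paste(unique(site[is.na(idx)]), collapse = ", "), "."))
  }
  list(epsilon = pairs$epsilon[idx], sigma = pairs$sigma[idx])
}

# lattice initial configuration, keeping solvent off the solute core
init_solvent <- function(spec, solute_xyz, clearance = 0.25) {
  n <- spec$n_solvent
  if (n == 0) return(matrix(numeric(0), 0, 3))
  k <- ceiling(n^(1 / 3))
  g <- (seq_len(k) - 0.5) / k * spec$box
  grid <- as.matrix(expand.grid(x = g, y = g, z = g))[seq_len(n), , drop = FALSE]
  # jitter breaks lattice symmetry; resample points overlapping the solute
  grid <- grid + matrix(runif(3 * n, -0.02, 0.02), n, 3)
  n_moved <- 0L
  if (nrow(solute_xyz) > 0) {
    for (j in seq_len(n)) {
      tries <- 0L
      while (min_dist_pbc(grid[j, ], solute_xyz, spec$box) < clearance &&
             tries < 200L) {
        grid[j, ] <- runif(3, 0, spec$box)
        tries <- tries + 1L
      }
      if (tries > 0L) n_moved <- n_moved + 1L
    }
  }
  attr(grid, "n_moved") <- n_moved
  grid
}

min_dist_pbc <- function(p, pts, box) {
  d <- sweep(pts, 2, p)
  d <- d - box * round(d / box)
  sqrt(min(rowSums(d^2)))
}

#' Run the toy Monte Carlo coupling simulation
#'
#' Metropolis sampling of the solvent around the rigid solute at each lambda
#' window of the schedule, carrying the configuration from window to window.
#' At every retained configuration the potential-energy gap to the adjacent
#' window, `dU = U(lam_next) - U(lam)`, and the box volume are recorded:
#' exactly the per-window samples the perturbation estimator consumes.
#' Identical seeds give bit-identical output.
#'
#' @param spec A [sim_spec()].
#' @param solute Solute geometry from [build_alkane_chain()].
#' @param pairs Cross-pair tibble (`name`, `epsilon`, `sigma`), e.g. from
#'   [cross_pairs()]; names are matched to the solute's site labels (a
#'   trailing `":O"` is ignored).
#' @param schedule Window schedule from [lambda_schedule()].
#' @param direction `"forward"` (0 to 1) or `"reverse"` (1 to 0).
#' @return List of class `mc_run`: `samples` (tibble `lam_i`, `lam_j`, `dU`,
#'   `V`), `acceptance` (mean move acceptance), `energy_drift` (max absolute
#'   bookkeeping error, kJ/mol), `final` (last configuration), `spec`,
#'   `n_overlap_moved` (initial-overlap resolutions, reported not hidden).
#' @export
mc_run <- function(spec, solute = build_alkane_chain(1), pairs,
                   schedule = lambda_schedule(),
                   direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  stopifnot(inherits(spec, "sim_spec"))
  pp <- pairs_for_sites(solute$site, pairs)
  set.seed(spec$seed)
  solute_xyz <- cbind(solute$x, solute$y, solute$z)
  solute_xyz <- sweep(solute_xyz, 2, spec$box / 2 - colMeans(solute_xyz), "+")
  solv <- init_solvent(spec, solute_xyz)
  n_moved <- attr(solv, "n_moved") %||% 0L

  wins <- if (direction == "forward") {
    tibble(lam = schedule$lam_i, other = schedule$lam_j)
  } else {
    tibble(lam = rev(schedule$lam_j), other = rev(schedule$lam_i))
  }

  samples <- vector("list", nrow(wins))
  acc <- drift <- numeric(nrow(wins))
  for (w in seq_len(nrow(wins))) {
    res <- cpp_run_window(
      solv, solute_xyz, pp$epsilon, pp$sigma,
      spec$eps_solvent, spec$sigma_solvent, spec$box,
      spec$rc_cross, spec$rc_solvent, spec$shift_cross, spec$shift_solvent,
      wins$lam[w], wins$other[w], spec$alpha, spec$n_exp,
      kT(spec$temperature), spec$n_sweeps, spec$n_burnin, spec$sample_every,
      spec$max_displacement, FALSE, 0L,
      spec$npt, spec$pressure_red, spec$max_dlnV, spec$vol_every)
    solv <- res$solvent
    solute_xyz <- res$solute
    spec$box <- res$box
    samples[[w]] <- tibble(lam_i = wins$lam[w], lam_j = wins$other[w],
                           dU = res$dU, V = res$V)
    acc[w] <- res$acceptance
    drift[w] <- res$energy_drift
  }
  structure(list(
    samples = dplyr::bind_rows(samples),
    acceptance = mean(acc, na.rm = TRUE), energy_drift = max(drift),
    final = list(solvent = solv, solute = solute_xyz, box = spec$box),
    spec = spec, direction = direction, n_overlap_moved = n_moved
  ), class = "mc_run")
}

#' @export
print.mc_run <- function(x, ...) {
  cat("Toy MC run (", x$direction, "): ",
      length(unique(x$samples$lam_i)), " windows, ",
      nrow(x$samples), " samples, acceptance ",
      format(x$acceptance, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Sample equilibrium configurations at a fixed coupling
#'
#' Runs the same Metropolis sampler at a single lambda value and records
#' configuration frames, yielding the trajectories used for radial
#' distribution functions, Widom insertion and the brute-force correction
#' oracles. `lam = 0` gives the pure solvent.
#'
#' @inheritParams mc_run
#' @param lam Coupling value in `[0, 1]`.
#' @param n_frames Number of frames to record.
#' @param frame_every Sweeps between recorded frames.
#' @param n_equil Equilibration sweeps before recording.
#' @return List of class `toy_trajectory`: `frames` (list of N x 3
#'   matrices), `solute` (M x 3 matrix), `box`, `lam`, `spec`.
#' @export
mc_sample_frames <- function(spec, solute = build_alkane_chain(1), pairs,
                             lam = 1, n_frames = 100, frame_every = 2,
                             n_equil = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  pp <- pairs_for_sites(solute$site, pairs)
  if (is.null(n_equil)) n_equil <- spec$n_burnin
  set.seed(spec$seed)
  solute_xyz <- cbind(solute$x, solute$y, solute$z)
  solute_xyz <- sweep(solute_xyz, 2, spec$box / 2 - colMeans(solute_xyz), "+")
  solv <- init_solvent(spec, solute_xyz)
  res <- cpp_run_window(
    solv, solute_xyz, pp$epsilon, pp$sigma,
    spec$eps_solvent, spec$sigma_solvent, spec$box,
    spec$rc_cross, spec$rc_solvent, spec$shift_cross, spec$shift_solvent,
    lam, lam, spec$alpha, spec$n_exp,
    kT(spec$temperature), n_equil + n_frames * frame_every, n_equil, 0L,
    spec$max_displacement, TRUE, frame_every,
    spec$npt, spec$pressure_red, spec$max_dlnV, spec$vol_every)
  structure(list(frames = res$frames, solute = res$solute, box = res$box,
                 lam = lam, sites = solute$site, spec = spec,
                 energy_drift = res$energy_drift),
            class = "toy_trajectory")
}

#' @export
print.toy_trajectory <- function(x, ...) {
  cat("Toy trajectory: ", length(x$frames), " frames, ",
      nrow(x$frames[[1]]), " solvent particles, box ",
      format(x$box, digits = 4), " nm, lambda = ", x$lam, "\n", sep = "")
  invisible(x)
}

#' Widom test-particle excess chemical potential
#'
#' Inserts the solute at uniform random positions and orientations into
#' solvent frames sampled with a lambda-independent Hamiltonian and
#' Boltzmann-averages the insertion energies:
#' `mu_ex = -kT ln < exp(-U_ins / kT) >`. The frame-to-frame spread of the
#' average gives the quoted standard error.
#'
#' @param traj A `toy_trajectory` of pure solvent ([mc_sample_frames()] at
#'   `lam = 0`).
#' @param solute,pairs Solute geometry and cross pairs, as in [mc_run()].
#' @param n_insertions Insertions per frame (>= 1).
#' @param seed Optional seed for the insertion stream.
#' @return Tibble with `mu_excess` (kJ/mol), `se` (kJ/mol, delta-method over
#'   frames), `n_insertions`.
#' @export
widom_mu_excess <- function(traj, solute = build_alkane_chain(1), pairs,
                            n_insertions = 2000, seed = NULL) {
  stopifnot(inherits(traj, "toy_trajectory"))
  if (n_insertions < 1) abort("`n_insertions` must be >= 1.")
  if (!is.null(seed)) set.seed(seed)
  pp <- pairs_for_sites(solute$site, pairs)
  spec <- traj$spec
  ktv <- kT(spec$temperature)
  rel <- cbind(solute$x, solute$y, solute$z)
  rel <- sweep(rel, 2, colMeans(rel))
  per_frame <- purrr::map_dbl(traj$frames, function(fr) {
    e <- cpp_insertion_energies(fr, rel, pp$epsilon, pp$sigma, traj$box,
                                spec$rc_cross, spec$shift_cross,
                                spec$alpha, spec$n_exp, as.integer(n_insertions))
    mean(exp(-e / ktv))
  })
  m <- mean(per_frame)
  se_m <- sd(per_frame) / sqrt(length(per_frame))
  tibble(mu_excess = -ktv * log(m), se = ktv * se_m / m,
         n_insertions = length(per_frame) * n_insertions)
}

#' Closed-form dilute-limit excess chemical potential
#'
#' In the low-density limit the excess chemical potential of inserting one
#' solute site into an ideal solvent reduces to a single Mayer-function
#' integral, `mu_ex = kT rho Int (1 - exp(-u(r)/kT)) 4 pi r^2 dr`, evaluated
#' here by adaptive quadrature over the same (optionally truncated/shifted)
#' potential the simulator uses. Serves as an independent acceptance oracle
#' for the coupling estimators.
#'
#' @param pair Cross-pair parameters.
#' @param rho Solvent number density, nm^-3.
#' @param temperature Temperature, K.
#' @param rc Cutoff applied to the pair potential (`Inf` for none).
#' @param shifted Shift the potential at `rc`?
#' @return `mu_ex` in kJ/mol. Warns when `rho` times the Mayer volume is
#'   large enough that the linear-in-density form is doubtful.
#' @export
low_density_mu_excess <- function(pair, rho, temperature = 300, rc = Inf,
                                  shifted = FALSE) {
  p <- as_pair(pair)
  ktv <- kT(temperature)
  u <- function(r) {
    base <- lj_energy(r, p)
    if (shifted && is.finite(rc)) base - lj_energy(rc, p) else base
  }
  integrand <- function(r) {
    val <- (1 - exp(-u(r) / ktv)) * 4 * pi * r^2
    val[r >= rc] <- 0
    val
  }
  upper <- if (is.finite(rc)) rc else Inf
  core <- integrate(integrand, 0, p$sigma, rel.tol = 1e-10,
                    subdivisions = 1000L, stop.on.error = TRUE)
  tail_part <- integrate(integrand, p$sigma, upper, rel.tol = 1e-10,
                         subdivisions = 1000L, stop.on.error = TRUE)
  mayer_vol <- core$value + tail_part$value
  if (rho * abs(mayer_vol) > 0.25) {
    warn("rho * B2-like volume is not small; the dilute-limit form may be inaccurate.")
  }
  ktv * rho * mayer_vol
}

#' Synthetic Gaussian window samples
#'
#' Seeded Gaussian energy gaps with constant or log-normal volumes, the
#' fixture for validating the estimator against the Gaussian closed form
#' `dg -> mu - sd^2 / (2 kT)`.
#'
#' @param mu,sd Mean and standard deviation of the gaps, kJ/mol (`sd >= 0`).
#' @param n Number of samples.
#' @param seed Optional seed.
#' @param lam_i,lam_j Window labels.
#' @param v_mode `"constant"` or `"lognormal"`.
#' @param v_mean Mean volume, nm^3.
#' @param v_sdlog Log-sd of the volume for `"lognormal"`.
#' @return Samples tibble (`lam_i`, `lam_j`, `dU`, `V`).
#' @export
gaussian_gap_samples <- function(mu, sd, n, seed = NULL, lam_i = 0, lam_j = 1,
                                 v_mode = c("constant", "lognormal"),
                                 v_mean = 1, v_sdlog = 0.05) {
  v_mode <- match.arg(v_mode)
  if (sd < 0) abort("`sd` must be >= 0.")
  if (n < 1) abort("`n` must be >= 1.")
  if (!is.null(seed)) set.seed(seed)
  dU <- rnorm(n, mu, sd)
  V <- if (v_mode == "constant") rep(v_mean, n)
       else v_mean * exp(rnorm(n, 0, v_sdlog) - v_sdlog^2 / 2)
  tibble(lam_i = lam_i, lam_j = lam_j, dU = dU, V = V)
}

#' Write a trajectory in XYZ format
#'
#' Plain-text XYZ: one block per frame, solvent sites labelled `S`, solute
#' sites by their united-atom labels, coordinates in nm.
#'
#' @param traj A `toy_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "toy_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  m <- nrow(traj$solute)
  for (fr in traj$frames) {
    n <- nrow(fr) + m
    writeLines(c(as.character(n), paste0("box_nm ", format(traj$box))), con)
    if (m > 0) {
      writeLines(sprintf("%s %.6f %.6f %.6f", traj$sites,
                         traj$solute[, 1], traj$solute[, 2], traj$solute[, 3]),
                 con)
    }
    writeLines(sprintf("S %.6f %.6f %.6f", fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(path)
}
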