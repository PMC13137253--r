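test_that("all-trans chain geometry matches the closed-form extension", {
  one <- build_alkane_chain(1)
  expect_equal(nrow(one), 1)
  expect_equal(c(one$x, one$y, one$z), c(0, 0, 0))
  two <- build_alkane_chain(2)
  expect_equal(sqrt(diff(two$x)^2 + diff(two$y)^2 + diff(two$z)^2), 0.154)
  c20 <- build_alkane_chain(20)
  expect_equal(nrow(c20), 20)
  # bond lengths and internal angles
  bonds <- cbind(diff(c20$x), diff(c20$y), diff(c20$z))
  expect_equal(sqrt(rowSums(bonds^2)), rep(0.154, 19))
  cosang <- sapply(seq_len(18), function(i) {
    sum(-bonds[i, ] * bonds[i + 1, ]) / (0.154^2)
  })
  expect_equal(cosang, rep(cos(114 * pi / 180), 18))
  # closed-form all-trans end-to-end distance
  th <- 114 * pi / 180
  n_bonds <- 19
  dx <- n_bonds * 0.154 * sin(th / 2)
  dy <- (n_bonds %% 2) * 0.154 * cos(th / 2)
  ee <- sqrt((c20$x[20] - c20$x[1])^2 + (c20$y[20] - c20$y[1])^2)
  expect_equal(ee, sqrt(dx^2 + dy^2))
})

test_that("identical seeds give bit-identical window samples", {
  spec <- sim_spec(n_solvent = 40, density = 8, seed = 77, n_sweeps = 40,
                   rc_cross = 0.8, rc_solvent = 0.8)
  sched <- lambda_schedule(0.25)
  r1 <- mc_run(spec, methane(), spce_pairs(), sched)
  r2 <- mc_run(spec, methane(), spce_pairs(), sched)
  expect_identical(r1$samples, r2$samples)
  r3 <- mc_run(sim_spec(n_solvent = 40, density = 8, seed = 78,
                        n_sweeps = 40, rc_cross = 0.8, rc_solvent = 0.8),
               methane(), spce_pairs(), sched)
  expect_false(identical(r1$samples$dU, r3$samples$dU))
})

test_that("an empty solvent yields identically zero gaps and free energy", {
  spec <- sim_spec(n_solvent = 0, density = 8, seed = 1, n_sweeps = 20,
                   rc_cross = 0.1, rc_solvent = 0.1)
  run <- mc_run(spec, methane(), spce_pairs(), lambda_schedule(0.25))
  expect_true(all(run$samples$dU == 0))
  expect_equal(fep_accumulate(run$samples, 300)$total, 0)
})

test_that("running energy bookkeeping matches full recomputation", {
  spec <- sim_spec(n_solvent = 60, density = 8, seed = 13, n_sweeps = 80,
                   rc_cross = 0.9, rc_solvent = 0.9)
  run <- mc_run(spec, build_alkane_chain(3), spce_pairs(),
                lambda_schedule(0.25))
  expect_lt(run$energy_drift, 1e-8)
  expect_gt(run$acceptance, 0.2) # moves actually move
  expect_lt(run$acceptance, 0.95)
})

test_that("NPT volume moves keep volumes positive and exercise the volume weighting", {
  spec <- sim_spec(n_solvent = 40, density = 8, seed = 21, n_sweeps = 120,
                   rc_cross = 0.8, rc_solvent = 0.8, npt = TRUE,
                   max_dlnV = 0.05, vol_every = 2)
  run <- mc_run(spec, methane(), spce_pairs(), lambda_schedule(0.5))
  expect_true(all(run$samples$V > 0))
  expect_gt(length(unique(run$samples$V)), 1) # volume really fluctuates
  expect_lt(run$energy_drift, 1e-8)
  res <- fep_accumulate(run$samples, 300)
  expect_true(is.finite(res$total))
})

test_that("a phantom solute inserts at zero cost", {
  traj <- toy_traj_solvent()
  ghost <- tibble::tibble(name = "CH4:O", epsilon = 0, sigma = 0.3)
  w <- widom_mu_excess(traj, methane(), ghost, n_insertions = 200, seed = 4)
  expect_equal(w$mu_excess, 0)
})

test_that("the dilute-limit integral vanishes without attraction and matches MC quadrature", {
  expect_equal(low_density_mu_excess(pair_par(0, 0.3), rho = 1), 0)
  p <- pair_par(0.65, 0.3166)
  ktv <- kT(300)
  set.seed(99)
  # brute-force Monte Carlo integration of the same Mayer integral
  R <- 2.0
  r <- R * runif(4e5)^(1 / 3)
  mc <- mean((1 - exp(-lj_energy(r, p) / ktv))) * 4 / 3 * pi * R^3
  rho <- 0.4
  expect_equal(low_density_mu_excess(p, rho, 300, rc = R), ktv * rho * mc,
               tolerance = 0.02)
  expect_warning(low_density_mu_excess(p, rho = 200, 300), "dilute")
})

test_that("a two-particle trajectory bins into the single correct RDF shell", {
  d <- 0.53
  solute <- matrix(c(1, 1, 1), 1, 3)
  frames <- list(matrix(c(1 + d, 1, 1), 1, 3))
  traj <- fake_traj(frames, solute, box = 4)
  rdf <- compute_rdf(traj, bin_width = 0.05)
  hit <- which(rdf$g > 0)
  expect_length(hit, 1)
  expect_lt(abs(rdf$r[hit] - d), 0.05 / 2 + 1e-12)
})

test_that("an ideal-gas solvent has unit pair correlation within counting error", {
  spec <- sim_spec(n_solvent = 150, density = 8, seed = 31, n_sweeps = 150,
                   eps_solvent = 0, rc_cross = 1.2, rc_solvent = 1.2)
  traj <- mc_sample_frames(spec, methane(), spce_pairs(), lam = 0,
                           n_frames = 120, frame_every = 1)
  rdf <- compute_rdf(traj, "solvent", bin_width = 0.1)
  bw <- attr(rdf, "bin_width")
  rho <- attr(rdf, "rho")
  n_pairs_expect <- attr(rdf, "n_frames") * 150 * rho * 4 / 3 * pi *
    ((rdf$r + bw / 2)^3 - (rdf$r - bw / 2)^3)
  keep <- rdf$r > 0.2 # tiny shells have too few counts for the normal limit
  sigma_g <- sqrt(n_pairs_expect) / n_pairs_expect
  expect_true(all(abs(rdf$g[keep] - 1) < 4 * sigma_g[keep] + 0.02))
})

test_that("RDF closure recovers the directly counted neighbour number", {
  traj <- toy_traj_coupled()
  rdf <- compute_rdf(traj, "solvent", bin_width = 0.02)
  bw <- attr(rdf, "bin_width")
  rho <- attr(rdf, "rho")
  r_max <- max(rdf$r) + bw / 2
  from_rdf <- sum(rho * rdf$g * 4 / 3 * pi *
                    ((rdf$r + bw / 2)^3 - (rdf$r - bw / 2)^3))
  # direct average neighbour count within r_max
  direct <- mean(sapply(traj$frames, function(fr) {
    n <- nrow(fr)
    cnt <- 0
    for (i in seq_len(n - 1)) {
      dd <- sweep(fr[(i + 1):n, , drop = FALSE], 2, fr[i, ])
      dd <- dd - traj$box * round(dd / traj$box)
      cnt <- cnt + sum(rowSums(dd^2) < r_max^2)
    }
    2 * cnt / n
  }))
  expect_equal(from_rdf, direct, tolerance = 1e-6)
})

test_that("the coupled-state solvent structure is near-ideal beyond the first shell", {
  rdf <- compute_rdf(toy_traj_coupled(), "cross", bin_width = 0.04)
  # past the first peak and trough only weak oscillations remain (the faint
  # second shell of the toy fluid peaks near 1.1)
  beyond <- rdf$r > 0.55 & rdf$r < 1.4
  expect_true(all(abs(rdf$g[beyond] - 1) < 0.12))
  expect_lt(mean(abs(rdf$g[beyond] - 1)), 0.05)
  expect_true(all(rdf$g[rdf$r < 0.25] == 0)) # excluded core
})

test_that("synthetic Gaussian gaps honour their moments and seeding", {
  s0 <- gaussian_gap_samples(2.5, 0, 40)
  expect_true(all(s0$dU == 2.5))
  a <- gaussian_gap_samples(1, 2, 100, seed = 5)
  b <- gaussian_gap_samples(1, 2, 100, seed = 5)
  expect_identical(a, b)
  expect_error(gaussian_gap_samples(1, -1, 10), "sd")
})

test_that("trajectories serialise to XYZ with one block per frame", {
  traj <- fake_traj(list(matrix(runif(9, 0, 2), 3, 3),
                         matrix(runif(9, 0, 2), 3, 3)),
                    matrix(c(1, 1, 1), 1, 3), box = 2)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(traj, path)
  lines <- readLines(path)
  expect_equal(sum(lines == "4"), 2) # 3 solvent + 1 solute, twice
  expect_equal(length(lines), 2 * (2 + 4))
})
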