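test_that("configuration merging rejects unknown keys but honours overrides", {
  cfg <- load_config(list(seed = 9, fep = list(n_solvent = 50)))
  expect_equal(cfg$seed, 9)
  expect_equal(cfg$fep$n_solvent, 50)
  expect_equal(cfg$fep$delta, 0.025)      # protocol default intact
  expect_equal(cfg$fep$rc_cross, 1.4)
  expect_equal(cfg$fep$replicates, 3L)
  expect_error(load_config(list(sead = 1)), "unknown config key")
  expect_error(load_config(list(fep = list(nsolvent = 1))), "unknown config\\$fep")
})

test_that("the reparameterization pipeline reproduces the printed predictions", {
  out_dir <- withr::local_tempdir()
  rep <- run_reparam(out_dir = out_dir)
  files <- list.files(out_dir)
  expect_setequal(files, c("hydration_table.csv", "updated_epsilon.csv",
                           "fit_log.txt"))
  first <- readLines(file.path(out_dir, "hydration_table.csv"), n = 1)
  expect_match(first, "^# seed: 1  config_hash: ")
  back <- utils::read.csv(file.path(out_dir, "hydration_table.csv"),
                          comment.char = "#")
  expect_equal(back$dg_pred, printed_hydration_ref()$dg_pred, tolerance = 0.02 / 10)
  # outputs are protected against silent overwrites
  expect_error(run_reparam(out_dir = out_dir), "overwrite")
  expect_silent(run_reparam(out_dir = out_dir, overwrite = TRUE))
})

test_that("user hydration tables go through the same pipeline, with clear errors", {
  out_dir <- withr::local_tempdir()
  s_true <- 1.12
  csv <- file.path(out_dir, "user.csv")
  readr::write_csv(tibble::tibble(
    n_carbons = c(1L, 3L), dg_cavity = c(25, 45),
    dh_att_model = c(-16, -36),
    dg_hyd_exp = c(25, 45) + s_true * c(-16, -36)), csv)
  rep <- run_reparam(list(reparam = list(reference = csv)),
                     out_dir = file.path(out_dir, "run"))
  expect_equal(rep$fit$s, s_true, tolerance = 1e-12)
  bad <- file.path(out_dir, "bad.csv")
  writeLines(c("n_carbons,dg_hyd_exp", "1,8.37"), bad)
  expect_error(run_reparam(list(reparam = list(reference = bad)),
                           out_dir = file.path(out_dir, "run2")),
               "dg_cavity")
})

test_that("the toy FEP pipeline is deterministic under a fixed seed", {
  cfg <- list(seed = 5,
              fep = list(n_solvent = 30L, density = 8, n_sweeps = 40L,
                         delta = 0.25, replicates = 2L,
                         rc_cross = 0.7, rc_solvent = 0.7))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- run_fep(cfg, out_dir = d1)
  r2 <- run_fep(cfg, out_dir = d2)
  expect_identical(r1$summary$mean, r2$summary$mean)
  expect_identical(r1$per_window$dg, r2$per_window$dg)
  expect_setequal(list.files(d1), c("fep_windows.tsv", "fep_summary.csv"))
  expect_equal(nrow(r1$summary), 2)
  expect_true(all(is.finite(r1$summary$sd)))
})

test_that("a zero-solvent FEP config yields a zero total", {
  cfg <- list(seed = 2,
              fep = list(n_solvent = 0L, density = 8, n_sweeps = 20L,
                         delta = 0.5, replicates = 2L,
                         rc_cross = 0.05, rc_solvent = 0.05))
  res <- run_fep(cfg, out_dir = withr::local_tempdir())
  expect_equal(res$summary$mean, c(0, 0))
})

test_that("the corrections pipeline honours a uniform synthetic RDF exactly", {
  out_dir <- withr::local_tempdir()
  rdf_path <- file.path(out_dir, "flat.tsv")
  r <- seq(0.001, 1.5, by = 0.001)
  write_rdf(rdf_table(r, rep(1, length(r))), rdf_path)
  cfg <- list(seed = 3,
              corrections = list(rdf_file = rdf_path, n_carbons = 6L,
                                 rc = 1.4, density = 8))
  out <- run_corrections(cfg, out_dir = file.path(out_dir, "run"))
  expect_setequal(out$prefactor, c("half", "full"))
  half <- out[out$prefactor == "half", ]
  closed <- half$n_sites * 8 * half$u_rc * (2 * pi / 3) * 1.4^3
  expect_equal(half$shift_rdf, closed, tolerance = 1e-4)
  expect_equal(out$shift_rdf[out$prefactor == "full"], 2 * half$shift_rdf)
  # cutoff in the attractive region: negative shift and tail terms
  expect_lt(half$u_rc, 0)
  expect_lt(half$tail, 0)
})

test_that("corrections refuse an RDF shorter than the cutoff", {
  out_dir <- withr::local_tempdir()
  rdf_path <- file.path(out_dir, "short.tsv")
  r <- seq(0.01, 0.8, by = 0.01)
  write_rdf(rdf_table(r, rep(1, length(r))), rdf_path)
  cfg <- list(corrections = list(rdf_file = rdf_path, rc = 1.4))
  expect_error(run_corrections(cfg, out_dir = file.path(out_dir, "run")),
               "shorter than the cutoff")
})

test_that("plot builders return ggplot objects", {
  res <- fep_accumulate(rbind(
    gaussian_gap_samples(1, 0.1, 30, seed = 1, lam_i = 0, lam_j = 0.5),
    gaussian_gap_samples(0.5, 0.1, 30, seed = 2, lam_i = 0.5, lam_j = 1)), 300)
  expect_s3_class(autoplot(res), "ggplot")
  r <- seq(0.05, 1, by = 0.05)
  expect_s3_class(autoplot(rdf_table(r, rep(1, 20))), "ggplot")
  rep <- build_reparam_table(load_reference(), spce_pairs())
  expect_s3_class(plot_reparam(rep), "ggplot")
})
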