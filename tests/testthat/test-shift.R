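test_that("mean energy from a uniform RDF matches square-well and zero closed forms", {
  r <- seq(0.001, 1.5, by = 0.001)
  rdf1 <- rdf_table(r, rep(1, length(r)))
  rho <- 10
  expect_equal(mean_energy_from_rdf(rdf1, function(r) 0 * r, 3, rho, 1.4), 0)
  a <- 0.3; b <- 0.9; depth <- 0.5
  sw <- function(r) ifelse(r >= a & r <= b, -depth, 0)
  closed <- -3 * rho * depth * (2 * pi / 3) * (b^3 - a^3)
  # trapezoid tolerance is set by the jump discontinuities at the well edges
  expect_equal(mean_energy_from_rdf(rdf1, sw, 3, rho, 1.4), closed,
               tolerance = 5e-3)
  expect_equal(mean_energy_from_rdf(rdf1, sw, 3, rho, 1.4, "full"),
               2 * closed, tolerance = 5e-3)
  short <- rdf_table(seq(0.01, 0.8, by = 0.01), rep(1, 80))
  expect_error(mean_energy_from_rdf(short, sw, 3, rho, 1.4), "extends only")
})

test_that("shift term from a uniform RDF matches its closed form and is bilinear", {
  r <- seq(0.001, 1.4, by = 0.001)
  rdf1 <- rdf_table(r, rep(1, length(r)))
  rho <- 8; rc <- 1.4; u_rc <- -0.02; n <- 6
  closed <- n * rho * u_rc * (2 * pi / 3) * rc^3
  got <- shift_energy_from_rdf(rdf1, u_rc, n, rho, rc)
  expect_equal(got, closed, tolerance = 1e-5)
  expect_equal(shift_energy_from_rdf(rdf1, 0, n, rho, rc), 0)
  expect_equal(shift_energy_from_rdf(rdf1, 3 * u_rc, n, rho, rc), 3 * got,
               tolerance = 1e-12)
  expect_equal(shift_energy_from_rdf(rdf1, u_rc, n, 5 * rho, rc), 5 * got,
               tolerance = 1e-12)
  expect_equal(shift_energy_from_rdf(rdf1, u_rc, n, rho, rc, "full"), 2 * got)
})

test_that("the analytic approximation reduces exactly to the uniform-RDF form", {
  rho <- 8; rc <- 1.4; u_rc <- -0.05
  for (n in c(1, 6, 20)) {
    expect_equal(shift_energy_approx(u_rc, n, 1, rho, rc, 0),
                 n * rho * u_rc * (2 * pi / 3) * rc^3)
  }
  # linear in u_rc
  base <- shift_energy_approx(u_rc, 10, 8, rho, rc, 0.35)
  expect_equal(shift_energy_approx(2 * u_rc, 10, 8, rho, rc, 0.35), 2 * base)
  expect_error(shift_energy_approx(u_rc, 5, 1, rho, rc = 0.3, sigma = 0.35),
               "exceed")
  expect_error(shift_energy_approx(u_rc, 5, 9, rho, rc, 0.2), "n_within")
  # per-site-type sum equals the hand-evaluated sum of its terms
  per <- shift_energy_approx(u_rc, c(2, 4), 6, rho, rc, c(0.36, 0.37))
  hand <- sum(c(2, 4) * rho * u_rc * (2 * pi / 3) *
                ((rc - c(0.36, 0.37))^3 - 5 * c(0.36, 0.37)^3))
  expect_equal(per, hand)
})

test_that("RDF-based shift term equals the brute-force pairwise energy difference", {
  traj <- toy_traj_coupled()
  rdf <- compute_rdf(traj, bin_width = 0.02)
  rho <- attr(rdf, "rho")
  p <- spce_pairs()[spce_pairs()$name == "CH4:O", ]
  rc <- 0.9
  u_rc <- lj_energy(rc, p)
  # per frame: plain minus shifted truncated cross energy = u(rc) * n_within
  pp <- pairs_for <- hydralk:::pairs_for_sites(methane()$site, spce_pairs())
  diff_bf <- mean(sapply(traj$frames, function(fr) {
    plain <- hydralk:::cpp_cross_energy(fr, traj$solute, pp$epsilon, pp$sigma,
                                        traj$box, 1, 0.5, 2L, rc, FALSE)
    shifted <- hydralk:::cpp_cross_energy(fr, traj$solute, pp$epsilon,
                                          pp$sigma, traj$box, 1, 0.5, 2L, rc,
                                          TRUE)
    plain - shifted
  }))
  eq_full <- shift_energy_from_rdf(rdf, u_rc, 1, rho, rc, "full")
  eq_half <- shift_energy_from_rdf(rdf, u_rc, 1, rho, rc, "half")
  expect_equal(eq_full, diff_bf, tolerance = 0.05)
  expect_equal(eq_half, diff_bf / 2, tolerance = 0.05)
})

test_that("RDF-based mean energy equals the brute-force frame average", {
  traj <- toy_traj_coupled()
  rdf <- compute_rdf(traj, bin_width = 0.02)
  rho <- attr(rdf, "rho")
  p <- spce_pairs()[spce_pairs()$name == "CH4:O", ]
  rc <- 1.2
  pp <- hydralk:::pairs_for_sites(methane()$site, spce_pairs())
  e_bf <- mean(sapply(traj$frames, function(fr) {
    hydralk:::cpp_cross_energy(fr, traj$solute, pp$epsilon, pp$sigma,
                               traj$box, 1, 0.5, 2L, rc, FALSE)
  }))
  u_trunc <- function(r) ifelse(r <= rc, lj_energy(pmax(r, 1e-9), p), 0)
  e_rdf <- mean_energy_from_rdf(rdf, u_trunc, 1, rho, rc, "full")
  expect_equal(e_rdf, e_bf, tolerance = 0.08)
})

test_that("within-cutoff neighbour counts match direct enumeration", {
  expect_equal(count_within_cutoff(matrix(0, 1, 3), 1.4, "site_index"), 1)
  two <- build_alkane_chain(2)
  expect_equal(as.numeric(count_within_cutoff(two, 1.4)), 2)
  c20 <- build_alkane_chain(20)
  rc <- 1.4
  m <- cbind(c20$x, c20$y, c20$z)
  # independent double-loop enumeration
  counts <- sapply(seq_len(20), function(i) {
    sum(sqrt(colSums((t(m) - m[i, ])^2)) <= rc)
  })
  got <- count_within_cutoff(c20, rc)
  expect_equal(as.numeric(got), mean(counts))
  expect_equal(attr(got, "reported"), as.integer(round(mean(counts))))
  expect_equal(count_within_cutoff(c20, rc, "site_index", index = 10),
               counts[10])
  # end sites see fewer neighbours than mid-chain sites on a long chain
  expect_lt(counts[1], counts[10])
})

test_that("corrected shifted free energies assemble with the documented signs", {
  expect_equal(correct_shifted_dG(5.3, 0, 0), 5.3)
  expect_equal(correct_shifted_dG(5.3, -0.8, -0.2), 4.3)
  expect_error(correct_shifted_dG(Inf, 0, 0), "finite")
})

test_that("effective cross diameter reduces mixed chains as documented", {
  hexane <- build_alkane_chain(6)
  pairs <- spce_pairs()
  sig <- effective_cross_sigma(hexane, pairs)
  s_ch3 <- pairs$sigma[pairs$name == "CH3:O"]
  s_ch2 <- pairs$sigma[pairs$name == "CH2:O"]
  expect_equal(sig, (2 * s_ch3 + 4 * s_ch2) / 6)
  per <- effective_cross_sigma(hexane, pairs, "per_site")
  expect_equal(sort(per$n), c(2L, 4L))
  expect_setequal(per$sigma, c(s_ch3, s_ch2))
})
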