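test_that("Lorentz-Berthelot mixing reproduces the published cross well depths", {
  expected <- printed_mixed_eps()
  for (model in unique(expected$model)) {
    got <- cross_pairs(model)
    want <- expected[expected$model == model, ]
    expect_equal(round(got$epsilon[match(want$site, got$name)], 4),
                 want$epsilon,
                 info = model)
  }
})

test_that("mixing rule is symmetric and the self-mix is the identity", {
  a <- site_par("CH3", 98 * kB_kJ_mol_K, 0.375)
  b <- site_par("O-spce", 0.6497752, 0.3166)
  ab <- lorentz_berthelot(a, b)
  ba <- lorentz_berthelot(b, a)
  expect_equal(ab$epsilon, ba$epsilon)
  expect_equal(ab$sigma, ba$sigma)
  expect_equal(ab$origin, "LB")
  aa <- lorentz_berthelot(a, a)
  expect_equal(aa$epsilon, a$epsilon)
  expect_equal(aa$sigma, a$sigma)
  expect_error(site_par("X", -1, 0.3), "epsilon")
  expect_error(site_par("X", 1, 0), "sigma")
})

test_that("plain Lennard-Jones has its root at sigma and minimum -epsilon", {
  p <- pair_par(0.65, 0.3166)
  expect_equal(lj_energy(0.3166, p), 0)
  expect_equal(lj_energy(2^(1 / 6) * 0.3166, p), -0.65)
  # independent hand substitution
  sr6 <- (0.3166 / 0.5)^6
  expect_equal(lj_energy(0.5, p), 4 * 0.65 * (sr6^2 - sr6))
  expect_error(lj_energy(0, p), "r")
  expect_error(lj_energy(-1, p), "r")
})

test_that("soft-core potential collapses to LJ at full coupling and is finite at contact", {
  p <- pair_par(0.65, 0.3166)
  r <- seq(0.25, 1.2, by = 0.05)
  expect_equal(softcore_energy(r, p, lam = 1), lj_energy(r, p))
  expect_equal(softcore_energy(r, p, lam = 0), rep(0, length(r)))
  # alpha (1-lam)^2 = 0.125 at lam = 0.5 -> eps (64 - 8) at contact
  expect_equal(softcore_energy(0, p, lam = 0.5), 56 * 0.65)
  # bounded at r = 0 for every partial coupling
  for (lam in seq(0.05, 0.95, by = 0.1)) {
    v <- softcore_energy(0, p, lam)
    expect_true(is.finite(v))
    expect_lte(abs(v), 4 * 0.65 / (0.5 * (1 - lam)^2)^2)
  }
  expect_error(softcore_energy(0.3, p, lam = 1.2), "lam")
  expect_error(softcore_energy(0.3, p, lam = -0.1), "lam")
})

test_that("soft-core at full coupling decays monotonically beyond the minimum", {
  p <- pair_par(0.8942, 0.3448)
  r <- seq(2^(1 / 6) * p$sigma, 3, length.out = 200)
  v <- softcore_energy(r, p, lam = 1)
  expect_true(all(diff(v) >= 0)) # energies rise toward 0: nonincreasing magnitude
  expect_true(all(v <= 0))
})

test_that("shifted potential vanishes at and beyond the cutoff, offset by u(rc) inside", {
  p <- pair_par(0.65, 0.3166)
  rc <- 0.9
  expect_equal(shifted_energy(rc, p, rc), 0)
  expect_equal(shifted_energy(1.1 * rc, p, rc), 0)
  rmin <- 2^(1 / 6) * p$sigma
  expect_equal(shifted_energy(rmin, p, rc), -0.65 - lj_energy(rc, p))
  r <- seq(0.28, rc, length.out = 50)
  expect_equal(shifted_energy(r, p, rc) - lj_energy(r, p),
               rep(-lj_energy(rc, p), length(r)))
})

test_that("tail correction matches direct quadrature of the truncated tail", {
  grid <- expand.grid(eps = c(0.3, 0.65, 1.0), sigma = c(0.3, 0.36, 0.4),
                      rc = c(0.9, 1.4, 2.0), rho = c(5, 33.3))
  for (i in seq_len(nrow(grid))) {
    gp <- grid[i, ]
    p <- pair_par(gp$eps, gp$sigma)
    oracle <- gp$rho * integrate(function(r) 2 * pi * r^2 * lj_energy(r, p),
                                 gp$rc, Inf, rel.tol = 1e-12)$value
    got <- tail_correction(1, gp$rho, p, gp$rc)
    expect_equal(got, oracle, tolerance = 1e-8)
    expect_equal(tail_correction(4, gp$rho, p, gp$rc), 4 * got)
    expect_equal(tail_correction(1, gp$rho, p, gp$rc, prefactor = "full"),
                 2 * got)
  }
})

test_that("tail correction vanishes for huge cutoffs and rejects bad ones", {
  p <- pair_par(0.65, 0.3166)
  expect_lt(abs(tail_correction(1, 33.3, p, 1e6 * p$sigma)), 1e-12)
  expect_lt(tail_correction(1, 33.3, p, 1.4), 0)
  expect_error(tail_correction(1, 33.3, p, -1), "rc")
  expect_error(tail_correction(1, 33.3, p, 0.2), "rc")
})

test_that("united-atom composition follows the homologous-series rule", {
  expect_equal(alkane_sites(1)$site, "CH4")
  s4 <- alkane_sites(4)$site
  expect_equal(sum(s4 == "CH3"), 2L)
  expect_equal(sum(s4 == "CH2"), 2L)
  for (n in c(2L, 7L, 20L)) {
    s <- alkane_sites(n)$site
    expect_length(s, n)
    expect_equal(sum(s == "CH3"), 2L)
    expect_equal(sum(s == "CH2"), n - 2L)
  }
  expect_error(alkane_sites(0), "n_carbons")
})

test_that("force-field files parse and the alkane parameters carry TraPPE values", {
  ff <- read_forcefield("trappe_ua")
  expect_equal(ff$epsilon, c(148, 98, 46) * kB_kJ_mol_K)
  expect_equal(ff$sigma, c(0.373, 0.375, 0.395))
  hh <- read_forcefield("hh_alkane")
  expect_true(all(is.na(hh$sigma))) # sigma deliberately unshipped
  expect_equal(hh$epsilon, c(0.9765, 0.7946, 0.5444))
  expect_error(read_forcefield("nonexistent"), "Unknown force field")
})
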