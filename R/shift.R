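# composite trapezoid on a discrete grid
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

pref_scale <- function(prefactor) {
  switch(match.arg(prefactor, c("half", "full")), half = 1, full = 2)
}

#' Mean solute-solvent interaction energy from a radial distribution function
#'
#' Integrates `N rho Int 2 pi r^2 g(r) u(r) dr` (trapezoid on the RDF grid)
#' for a truncated plain Lennard-Jones cross potential. The default `"half"`
#' prefactor is the 2 pi r^2 convention used consistently by this family of
#' corrections; `"full"` uses 4 pi r^2 and equals the brute-force pairwise
#' cross-energy average (see the methods vignette on the factor of two).
#'
#' @param rdf An `rdf_table` (columns `r`, `g`).
#' @param pair Cross-pair parameters for a plain Lennard-Jones `u(r)`, or a
#'   function `u(r)` returning kJ/mol for any other pair potential.
#' @param n_sites Number of solute united atoms N.
#' @param rho Solvent number density, nm^-3.
#' @param rc Cutoff of `u`; the RDF must extend to it.
#' @param prefactor `"half"` (default) or `"full"`.
#' @return Energy in kJ/mol.
#' @export
mean_energy_from_rdf <- function(rdf, pair, n_sites, rho, rc,
                                 prefactor = c("half", "full")) {
  sc <- pref_scale(prefactor)
  ufun <- if (is.function(pair)) pair else {
    p <- as_pair(pair)
    function(r) lj_energy(pmax(r, 1e-12), p)
  }
  check_rdf_domain(rdf, rc)
  keep <- rdf$r <= rc + 1e-12
  r <- rdf$r[keep]
  g <- rdf$g[keep]
  u <- ifelse(g > 0, ufun(r), 0) # g = 0 kills the repulsive core
  n_sites * rho * sc * trapz(r, 2 * pi * r^2 * g * u)
}

#' Energy change due to shifting the potential at the cutoff, from the RDF
#'
#' The exact (to binning) form of the shift contribution: every cross pair
#' inside the cutoff contributes the shift value `u(rc)`, so
#' `dE = N rho u(rc) Int_0^rc 2 pi r^2 g(r) dr`. Negative when the cutoff
#' sits in the attractive region.
#'
#' @inheritParams mean_energy_from_rdf
#' @param u_rc Pair potential value at the cutoff, kJ/mol.
#' @return Energy in kJ/mol.
#' @export
shift_energy_from_rdf <- function(rdf, u_rc, n_sites, rho, rc,
                                  prefactor = c("half", "full")) {
  sc <- pref_scale(prefactor)
  check_rdf_domain(rdf, rc)
  keep <- rdf$r <= rc + 1e-12
  r <- rdf$r[keep]
  g <- rdf$g[keep]
  n_sites * rho * u_rc * sc * trapz(r, 2 * pi * r^2 * g)
}

check_rdf_domain <- function(rdf, rc) {
  if (!all(c("r", "g") %in% names(rdf))) {
    abort("`rdf` must have columns `r` and `g`.")
  }
  if (max(rdf$r) < rc - 1e-9) {
    abort(paste0("RDF extends only to r = ", format(max(rdf$r), digits = 4),
                 " nm but the cutoff is ", format(rc, digits = 4), " nm."))
  }
  invisible(NULL)
}

#' Analytic approximation of the shift contribution
#'
#' Replaces the RDF integral by a step model - `g(r) = 1` beyond the site
#' diameter, 0 inside it - and subtracts the volume excluded by the other
#' united atoms of the chain:
#'
#'   `dE = N rho u(rc) (2 pi / 3) [ (rc - sigma)^3 - (Nw - 1) sigma^3 ]`
#'
#' where `Nw` is the number of united atoms within `rc` of a reference atom
#' (self included; see [count_within_cutoff()]). With `sigma = 0, Nw = 1`
#' this reduces exactly to the `g == 1` limit of [shift_energy_from_rdf()].
#' Vector `sigma`/`n_sites` inputs evaluate the per-site-type sum instead of
#' the single effective-diameter form.
#'
#' @param u_rc Pair potential at the cutoff, kJ/mol.
#' @param n_sites United-atom count N (scalar, or per-type counts).
#' @param n_within Within-cutoff neighbour count Nw (>= 1, <= total N).
#' @param rho Solvent number density, nm^-3.
#' @param rc Cutoff, nm (> sigma).
#' @param sigma Effective cross diameter, nm (scalar, or per-type).
#' @param prefactor `"half"` (default) or `"full"`.
#' @return Energy in kJ/mol.
#' @export
shift_energy_approx <- function(u_rc, n_sites, n_within, rho, rc, sigma,
                                prefactor = c("half", "full")) {
  sc <- pref_scale(prefactor)
  if (length(sigma) != length(n_sites)) {
    abort("`sigma` and `n_sites` must have equal length.")
  }
  if (any(rc <= sigma)) abort("`rc` must exceed `sigma`.")
  if (n_within < 1 || n_within > sum(n_sites)) {
    abort("`n_within` must lie in [1, sum(n_sites)].")
  }
  sum(n_sites * rho * u_rc * sc * (2 * pi / 3) *
        ((rc - sigma)^3 - (n_within - 1) * sigma^3))
}

#' Count united atoms within the cutoff of a reference atom
#'
#' The neighbour count entering [shift_energy_approx()]: how many united
#' atoms of the chain (the reference atom included) lie within `rc` of a
#' reference atom. `per_site_average` averages over all reference sites and
#' keeps the real-valued mean (the rounded integer is attached as attribute
#' `reported`); `site_index` counts for one chosen site.
#'
#' @param coords Solute coordinates: a tibble with `x`, `y`, `z` (e.g.
#'   [build_alkane_chain()]) or an M x 3 matrix.
#' @param rc Cutoff, nm.
#' @param mode `"per_site_average"` or `"site_index"`.
#' @param index Reference site for `"site_index"`.
#' @return Numeric count (real-valued for the average mode).
#' @examples
#' count_within_cutoff(build_alkane_chain(2), rc = 1.4) # 2
#' @export
count_within_cutoff <- function(coords, rc,
                                mode = c("per_site_average", "site_index"),
                                index = 1L) {
  mode <- match.arg(mode)
  m <- if (is.data.frame(coords)) cbind(coords$x, coords$y, coords$z)
       else as.matrix(coords)
  if (nrow(m) < 1L) abort("need at least one site.")
  d <- as.matrix(stats::dist(m))
  counts <- rowSums(d <= rc) # diagonal contributes the self count
  if (mode == "site_index") {
    if (index < 1L || index > nrow(m)) abort("`index` out of range.")
    return(counts[[index]])
  }
  out <- mean(counts)
  attr(out, "reported") <- as.integer(round(out))
  out
}

#' Assemble the corrected free energy of a shifted-potential run
#'
#' A run with shifted cross potentials samples a less attractive Hamiltonian
#' than the plain truncated one, so its coupling free energy is biased
#' upward by (to first order) minus the shift energy. The correction adds
#' the (negative) shift term of [shift_energy_from_rdf()] /
#' [shift_energy_approx()] and the (negative) long-range tail of
#' [tail_correction()]:
#'
#'   `dG_corrected = dG_shifted + shift_term + tail_term`
#'
#' First-order perturbation overestimates the magnitude of the shift's
#' free-energy effect, so the correction tends to overshoot slightly
#' downward relative to an unshifted run with the tail applied.
#'
#' @param dg_shifted Free energy from the shifted-potential run, kJ/mol.
#' @param shift_term Shift contribution (Eq.-6/7-style value, negative for
#'   an attractive cutoff), kJ/mol.
#' @param tail_term Long-range tail correction, kJ/mol.
#' @return Corrected free energy, kJ/mol.
#' @export
correct_shifted_dG <- function(dg_shifted, shift_term, tail_term) {
  vals <- c(dg_shifted, shift_term, tail_term)
  if (any(!is.finite(vals))) abort("all inputs must be finite.")
  dg_shifted + shift_term + tail_term
}

#' Effective cross diameter of a mixed-site chain
#'
#' The analytic shift approximation uses one site diameter for the whole
#' chain; for mixed CH3/CH2 chains the default reduction is the
#' site-count-weighted mean of the cross diameters (`method = "site_mean"`).
#' `method = "per_site"` returns the per-site-type diameters and counts so
#' the caller can evaluate the per-type sum in [shift_energy_approx()].
#'
#' @param sites Tibble of solute site labels (column `site`), e.g. from
#'   [build_alkane_chain()] or [alkane_sites()].
#' @param pairs Cross-pair tibble with `name` and `sigma`.
#' @param method `"site_mean"` or `"per_site"`.
#' @return For `"site_mean"`, a single sigma (nm); for `"per_site"`, a
#'   tibble with `site`, `n`, `sigma`.
#' @export
effective_cross_sigma <- function(sites, pairs,
                                  method = c("site_mean", "per_site")) {
  method <- match.arg(method)
  pp <- pairs_for_sites(sites$site, pairs)
  if (method == "site_mean") return(mean(pp$sigma))
  counts <- table(sites$site)
  idx <- match(names(counts), sites$site)
  tibble(site = names(counts), n = as.integer(counts),
         sigma = pp$sigma[idx])
}
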