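#' Lennard-Jones site and pair parameters
#'
#' A site is one united atom (CH4, CH3, CH2) or a water-model oxygen; a pair
#' holds the cross-interaction parameters entering the pair potential.
#' Both are plain one-row tibbles so they compose with dplyr verbs; every
#' energy function in the package also accepts a named list with `epsilon`
#' and `sigma` elements.
#'
#' @param name Site label, e.g. `"CH4"` or `"O-spce"`.
#' @param epsilon Well depth in kJ/mol (>= 0).
#' @param sigma Diameter in nm (> 0).
#' @param origin For pairs: `"LB"` when produced by the mixing rule,
#'   `"explicit"` when supplied directly.
#' @return A one-row tibble with columns `name`/`epsilon`/`sigma`
#'   (sites) or `epsilon`/`sigma`/`origin` (pairs).
#' @examples
#' site_par("CH4", epsilon = 148 * kB_kJ_mol_K, sigma = 0.373)
#' pair_par(epsilon = 0.65, sigma = 0.3166)
#' @export
site_par <- function(name, epsilon, sigma) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("`name` must be a nonempty string.")
  }
  check_eps_sigma(epsilon, sigma)
  tibble(name = name, epsilon = as.numeric(epsilon), sigma = as.numeric(sigma))
}

#' @rdname site_par
#' @export
pair_par <- function(epsilon, sigma, origin = "explicit") {
  check_eps_sigma(epsilon, sigma)
  tibble(epsilon = as.numeric(epsilon), sigma = as.numeric(sigma),
         origin = origin)
}

check_eps_sigma <- function(epsilon, sigma) {
  if (any(!is.finite(epsilon)) || any(epsilon < 0)) {
    abort("`epsilon` must be finite and >= 0 (kJ/mol).")
  }
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    abort("`sigma` must be finite and > 0 (nm).")
  }
  invisible(NULL)
}

# Accept a pair as a one-row data frame or a named list.
as_pair <- function(p) {
  if (is.data.frame(p)) {
    if (nrow(p) != 1L) abort("pair parameters must be a single row.")
    p <- as.list(p)
  }
  if (is.null(p$epsilon) || is.null(p$sigma)) {
    abort("pair parameters need `epsilon` and `sigma` fields.")
  }
  check_eps_sigma(p$epsilon, p$sigma)
  p
}

#' Lorentz-Berthelot mixing rule
#'
#' Cross-interaction parameters from the arithmetic mean of the diameters and
#' the geometric mean of the well depths of two sites.
#'
#' @param a,b Sites as returned by [site_par()] (or named lists with
#'   `epsilon`, `sigma`).
#' @return A pair tibble with `origin = "LB"`.
#' @examples
#' ch4 <- site_par("CH4", 148 * kB_kJ_mol_K, 0.373)
#' o <- site_par("O-spce", 0.1553 * 4.184, 0.3166)
#' lorentz_berthelot(ch4, o) # epsilon 0.8942 kJ/mol
#' @export
lorentz_berthelot <- function(a, b) {
  a <- as_pair(a)
  b <- as_pair(b)
  pair_par(epsilon = sqrt(a$epsilon * b$epsilon),
           sigma = (a$sigma + b$sigma) / 2,
           origin = "LB")
}

#' Mix every alkane site with a water oxygen site
#'
#' Applies [lorentz_berthelot()] row-wise, keeping the site labels, so the
#' result is the per-water-model cross-parameter table.
#'
#' @param sites Tibble of alkane sites (columns `name`, `epsilon`, `sigma`).
#' @param water One-row tibble for the water O site.
#' @return Tibble with one row per alkane site: `name`, `epsilon`, `sigma`,
#'   `origin`.
#' @export
mix_pairs <- function(sites, water) {
  water <- as_pair(water)
  check_eps_sigma(sites$epsilon, sites$sigma)
  tibble(
    name = sites$name,
    epsilon = sqrt(sites$epsilon * water$epsilon),
    sigma = (sites$sigma + water$sigma) / 2,
    origin = "LB"
  )
}

#' Pair potentials: plain, soft-core and shifted Lennard-Jones
#'
#' `lj_energy()` is the plain 12-6 form `4 eps [ (sigma/r)^12 - (sigma/r)^6 ]`.
#' `softcore_energy()` couples it to an alchemical parameter `lam` in `[0, 1]`:
#'
#'   `lam^n * 4 eps * [ (a(1-lam)^2 + (r/sigma)^6)^-2 - (a(1-lam)^2 + (r/sigma)^6)^-1 ]`
#'
#' which is finite at `r = 0` for any `lam < 1` (the soft core removes the
#' insertion singularity) and collapses to `lj_energy()` at `lam = 1`.
#' `shifted_energy()` subtracts the value at the cutoff so the potential
#' vanishes continuously at `rc` and is exactly zero beyond it.
#'
#' @param r Separation(s) in nm.
#' @param pair Pair parameters ([pair_par()] or named list).
#' @param lam Coupling parameter in `[0, 1]`; vectorised.
#' @param alpha Soft-core constant (> 0), default 0.5.
#' @param n_exp Integer lambda exponent (>= 1), default 2.
#' @param rc Spherical cutoff in nm.
#' @return Energy in kJ/mol, vectorised over `r` (and `lam`).
#' @examples
#' p <- pair_par(0.65, 0.3166)
#' lj_energy(2^(1/6) * 0.3166, p)          # -epsilon at the minimum
#' softcore_energy(0, p, lam = 0.5)        # finite at contact
#' shifted_energy(0.9, p, rc = 0.9)        # zero at the cutoff
#' @export
lj_energy <- function(r, pair) {
  p <- as_pair(pair)
  if (any(!is.finite(r)) || any(r <= 0)) abort("`r` must be finite and > 0 (nm).")
  sr6 <- (p$sigma / r)^6
  4 * p$epsilon * (sr6^2 - sr6)
}

#' @rdname lj_energy
#' @export
softcore_energy <- function(r, pair, lam, alpha = 0.5, n_exp = 2L) {
  p <- as_pair(pair)
  if (any(!is.finite(lam)) || any(lam < 0) || any(lam > 1)) {
    abort("`lam` must lie in [0, 1].")
  }
  if (!is.finite(alpha) || alpha <= 0) abort("`alpha` must be > 0.")
  n_exp <- as.integer(n_exp)
  if (is.na(n_exp) || n_exp < 1L) abort("`n_exp` must be an integer >= 1.")
  if (any(!is.finite(r)) || any(r < 0)) abort("`r` must be finite and >= 0 (nm).")
  denom <- alpha * (1 - lam)^2 + (r / p$sigma)^6
  out <- lam^n_exp * 4 * p$epsilon * (denom^-2 - denom^-1)
  # lam = 0 kills the prefactor even where denom -> 0 never happens (alpha>0)
  out[lam == 0] <- 0
  out
}

#' @rdname lj_energy
#' @export
shifted_energy <- function(r, pair, rc) {
  p <- as_pair(pair)
  if (!is.finite(rc) || rc <= 0) abort("`rc` must be finite and > 0 (nm).")
  if (any(!is.finite(r)) || any(r <= 0)) abort("`r` must be finite and > 0 (nm).")
  u_rc <- lj_energy(rc, p)
  ifelse(r <= rc, lj_energy(pmax(r, .Machine$double.xmin), p) - u_rc, 0)
}

#' Long-range (tail) correction for truncated alkane-water interactions
#'
#' Analytic estimate of the interaction energy beyond the cutoff assuming
#' uniform pair correlation (`g(r) = 1` for `r > rc`):
#'
#'   `E_LR = N rho 8 pi eps sigma^3 [ sigma^9 / (9 rc^9) - sigma^3 / (3 rc^3) ]`
#'
#' under the `"half"` (2 pi r^2) integration convention used consistently by
#' the corrections in this package; `"full"` doubles it (the 4 pi r^2
#' convention common elsewhere). See the methods vignette for the convention
#' discussion.
#'
#' @param n_sites Number of united atoms in the solute.
#' @param rho Solvent number density in nm^-3.
#' @param pair Cross-pair parameters.
#' @param rc Cutoff in nm (must exceed `sigma`).
#' @param prefactor `"half"` (default) or `"full"`.
#' @return Tail energy in kJ/mol (negative for an attractive tail).
#' @export
tail_correction <- function(n_sites, rho, pair, rc,
                            prefactor = c("half", "full")) {
  prefactor <- match.arg(prefactor)
  p <- as_pair(pair)
  if (!is.finite(rc) || rc <= 0) abort("`rc` must be finite and > 0 (nm).")
  if (rc <= p$sigma) abort("`rc` must exceed `sigma` for the tail form to apply.")
  if (!is.finite(rho) || rho < 0) abort("`rho` must be finite and >= 0 (nm^-3).")
  base <- n_sites * rho * 8 * pi * p$epsilon * p$sigma^3 *
    (p$sigma^9 / (9 * rc^9) - p$sigma^3 / (3 * rc^3))
  if (prefactor == "full") 2 * base else base
}

#' United-atom composition of a linear alkane
#'
#' Methane is a single CH4 site; longer alkanes have two CH3 ends and
#' `n - 2` CH2 middles.
#'
#' @param n_carbons Number of carbons (>= 1).
#' @return Tibble with columns `site` (one row per united atom, in chain
#'   order) and attribute-free counts accessible via `dplyr::count()`.
#' @examples
#' alkane_sites(4) # CH3, CH2, CH2, CH3
#' @export
alkane_sites <- function(n_carbons) {
  n_carbons <- as.integer(n_carbons)
  if (is.na(n_carbons) || n_carbons < 1L) abort("`n_carbons` must be >= 1.")
  site <- if (n_carbons == 1L) "CH4" else
    c("CH3", rep("CH2", n_carbons - 2L), "CH3")
  tibble(position = seq_len(n_carbons), site = site)
}
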