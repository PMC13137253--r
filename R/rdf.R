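#' Radial distribution function from a toy trajectory
#'
#' Standard binned pair histogram normalised by the ideal-gas shell count
#' and the number of frames and reference sites. `selection = "cross"` bins
#' solute-site to solvent distances (the solute-solvent g(r) consumed by the
#' correction integrals); `"solvent"` bins solvent-solvent distances.
#'
#' @param traj A `toy_trajectory` from [mc_sample_frames()].
#' @param selection `"cross"` or `"solvent"`.
#' @param bin_width Bin width, nm.
#' @param r_max Histogram range; defaults to (and may not exceed) half the
#'   box edge.
#' @return Tibble of class `rdf_table` with columns `r` (bin centres, nm)
#'   and `g`; attributes `bin_width`, `rho` (partner density used), and
#'   `n_frames`.
#' @export
compute_rdf <- function(traj, selection = c("cross", "solvent"),
                        bin_width = 0.02, r_max = NULL) {
  selection <- match.arg(selection)
  stopifnot(inherits(traj, "toy_trajectory"))
  if (bin_width <= 0) abort("`bin_width` must be > 0 (nm).")
  box <- traj$box
  if (is.null(r_max)) r_max <- floor((box / 2) / bin_width) * bin_width
  if (r_max > box / 2 + 1e-12) {
    abort("`r_max` must not exceed half the box edge.")
  }
  n_solv <- nrow(traj$frames[[1]])
  if (n_solv == 0) abort("trajectory has no solvent particles.")
  if (selection == "cross" && nrow(traj$solute) == 0) {
    abort("trajectory has no solute sites for a cross RDF.")
  }
  edges <- seq(0, r_max, by = bin_width)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  rho <- n_solv / box^3
  n_ref <- if (selection == "cross") nrow(traj$solute) else n_solv
  for (fr in traj$frames) {
    d <- if (selection == "cross") {
      cross_distances(traj$solute, fr, box)
    } else {
      self_distances(fr, box)
    }
    d <- d[d < r_max]
    counts <- counts + tabulate(pmin(floor(d / bin_width) + 1L, nb), nb)
  }
  shell_vol <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nb + 1L)]^3)
  # for same-species pairs each unordered pair is counted once; double it so
  # the reference-site normalisation below matches the ordered convention
  if (selection == "solvent") counts <- counts * 2
  g <- counts / (length(traj$frames) * n_ref * rho * shell_vol)
  out <- tibble(r = (edges[-1] + edges[-(nb + 1L)]) / 2, g = g)
  structure(out, class = c("rdf_table", class(out)),
            bin_width = bin_width, rho = rho,
            n_frames = length(traj$frames), selection = selection)
}

cross_distances <- function(ref, pts, box) {
  unlist(lapply(seq_len(nrow(ref)), function(k) {
    d <- sweep(pts, 2, ref[k, ])
    d <- d - box * round(d / box)
    sqrt(rowSums(d^2))
  }))
}

self_distances <- function(pts, box) {
  n <- nrow(pts)
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    d <- sweep(pts[(i + 1L):n, , drop = FALSE], 2, pts[i, ])
    d <- d - box * round(d / box)
    out[[i]] <- sqrt(rowSums(d^2))
  }
  unlist(out)
}

#' Read and write RDF tables as TSV
#'
#' Two-column plain text (`r_nm`, `g`), the interchange format for feeding
#' externally computed radial distribution functions into the correction
#' integrals.
#'
#' @param rdf An `rdf_table` (or any tibble with `r` and `g`).
#' @param path File path.
#' @param bin_width,rho Optional metadata to attach on read (bin width is
#'   inferred from the grid when omitted).
#' @return `read_rdf()` returns an `rdf_table`; `write_rdf()` returns
#'   `path` invisibly.
#' @export
write_rdf <- function(rdf, path) {
  readr::write_tsv(tibble(r_nm = rdf$r, g = rdf$g), path)
  invisible(path)
}

#' @rdname write_rdf
#' @export
read_rdf <- function(path, bin_width = NULL, rho = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (!all(c("r_nm", "g") %in% names(df))) {
    abort("RDF file must have columns `r_nm` and `g`.")
  }
  rdf_table(df$r_nm, df$g, bin_width = bin_width, rho = rho)
}

#' Construct an RDF table from vectors
#'
#' @param r Strictly increasing bin centres, nm.
#' @param g Nonnegative g(r) values.
#' @param bin_width,rho Optional metadata.
#' @return An `rdf_table` tibble.
#' @export
rdf_table <- function(r, g, bin_width = NULL, rho = NULL) {
  if (length(r) != length(g)) abort("`r` and `g` must have equal length.")
  if (any(diff(r) <= 0)) abort("`r` must be strictly increasing.")
  if (any(g < 0)) abort("`g` must be >= 0.")
  out <- tibble(r = r, g = g)
  structure(out, class = c("rdf_table", class(out)),
            bin_width = bin_width %||% (if (length(r) > 1) r[2] - r[1] else NA_real_),
            rho = rho)
}
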