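#' Cavity decomposition of the hydration free energy
#'
#' The hydration free energy splits as `dG_hyd = dG_cavity + dH_att`: the
#' (positive) cost of opening a solute-shaped cavity plus the (negative)
#' solute-solvent attraction enthalpy. Given an experimental `dG_hyd` and a
#' cavity term, the implied attraction enthalpy is the difference;
#' `predict_hydration()` is the inverse assembly.
#'
#' @param dg_hyd Hydration free energy, kJ/mol.
#' @param dg_cavity Cavity-formation free energy, kJ/mol.
#' @param dh_att Attraction enthalpy, kJ/mol.
#' @return kJ/mol; vectorised.
#' @examples
#' attraction_from_decomposition(8.37, 24.52) # methane: -16.15
#' predict_hydration(24.52, -15.96)           # 8.56
#' @export
attraction_from_decomposition <- function(dg_hyd, dg_cavity) {
  if (any(!is.finite(dg_hyd)) || any(!is.finite(dg_cavity))) {
    abort("inputs must be finite (kJ/mol).")
  }
  dg_hyd - dg_cavity
}

#' @rdname attraction_from_decomposition
#' @export
predict_hydration <- function(dg_cavity, dh_att) {
  if (any(!is.finite(dg_cavity)) || any(!is.finite(dh_att))) {
    abort("inputs must be finite (kJ/mol).")
  }
  dg_cavity + dh_att
}

#' Rescale a well depth from a single attraction-enthalpy ratio
#'
#' Under the assumption that the local solvent structure is unchanged by a
#' small well-depth perturbation, the attraction enthalpy is linear in the
#' cross epsilon, so matching a target enthalpy rescales epsilon by the
#' enthalpy ratio: `eps_updated = (dH_target / dH_model) * eps`.
#'
#' @param eps Current cross well depth, kJ/mol.
#' @param dh_target Target (e.g. experiment-derived) attraction enthalpy.
#' @param dh_model Model attraction enthalpy at the current epsilon.
#' @return Updated epsilon, kJ/mol.
#' @export
update_epsilon <- function(eps, dh_target, dh_model) {
  if (any(!is.finite(eps)) || any(!is.finite(dh_target)) ||
      any(!is.finite(dh_model))) abort("inputs must be finite.")
  if (any(dh_model == 0)) abort("`dh_model` must be nonzero.")
  if (any(sign(dh_target) != sign(dh_model))) {
    abort("`dh_target` and `dh_model` must share sign; the ratio is undefined otherwise.")
  }
  eps * dh_target / dh_model
}

#' Fit the global alkane-water well-depth scale factor
#'
#' One dimensionless factor `s` rescales every alkane-water epsilon so that
#' the model attraction enthalpies match the experiment-derived ones across
#' the homologous series. `mean_ratio` (default) averages the per-alkane
#' ratios `dh_att_exp / dh_att_model`; `weighted_ls` solves the
#' one-parameter least-squares problem `min_s sum (dh_exp - s dh_model)^2`,
#' i.e. `s = sum(dh_exp dh_model) / sum(dh_model^2)`, which weights long
#' alkanes (larger enthalpies) more heavily.
#'
#' @param records Data frame with columns `dh_att_exp` and `dh_att_model`
#'   (kJ/mol, both negative). Rows with either missing are dropped.
#' @param method `"mean_ratio"` or `"weighted_ls"`.
#' @return Object of class `scale_fit`: the scale `s`, per-alkane ratios and
#'   the method. Supports [tidy()], [glance()] and `print()`.
#' @examples
#' fit <- fit_global_scale(reparam_records(load_reference()))
#' glance(fit) # s about 1.055: the well depth rises by about 5%
#' @export
fit_global_scale <- function(records, method = c("mean_ratio", "weighted_ls")) {
  method <- match.arg(method)
  need <- c("dh_att_exp", "dh_att_model")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("`records` is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  keep <- stats::complete.cases(records[need])
  rec <- records[keep, ]
  if (nrow(rec) == 0) abort("no records with both dh_att_exp and dh_att_model.")
  if (any(rec$dh_att_model == 0)) abort("`dh_att_model` must be nonzero.")
  ratios <- rec$dh_att_exp / rec$dh_att_model
  if (any(ratios <= 0)) {
    abort("attraction enthalpies must share sign (ratios must be positive).")
  }
  s <- switch(method,
    mean_ratio = mean(ratios),
    weighted_ls = sum(rec$dh_att_exp * rec$dh_att_model) / sum(rec$dh_att_model^2)
  )
  structure(
    list(s = s, method = method,
         ratios = tibble(
           n_carbons = if ("n_carbons" %in% names(rec)) rec$n_carbons
                       else seq_len(nrow(rec)),
           ratio = ratios)),
    class = "scale_fit")
}

#' @export
print.scale_fit <- function(x, ...) {
  cat("Global well-depth scale fit (", x$method, ")\n", sep = "")
  cat("  s =", format(x$s, digits = 6), "from", nrow(x$ratios), "alkanes\n")
  invisible(x)
}

#' @export
tidy.scale_fit <- function(x, ...) x$ratios

#' @export
glance.scale_fit <- function(x, ...) {
  tibble(s = x$s, method = x$method, n = nrow(x$ratios),
         ratio_sd = sd(x$ratios$ratio))
}

#' Apply a fitted scale to cross pairs and hydration records
#'
#' Multiplies every cross-pair epsilon by the fitted scale and fills the
#' `dh_att_updated` column (`s * dh_att_model`) of the records, the linearity
#' in epsilon being the working assumption of the reparameterization.
#'
#' @param fit A `scale_fit` from [fit_global_scale()] (or a bare positive
#'   number).
#' @param pairs Optional tibble of cross pairs with an `epsilon` column.
#' @param records Optional data frame with `dh_att_model`.
#' @return A list with elements `pairs` (epsilon rescaled, original kept as
#'   `epsilon_original`) and `records` (with `dh_att_updated` and, when
#'   `dg_cavity` is present, `dg_pred`).
#' @export
apply_scale <- function(fit, pairs = NULL, records = NULL) {
  s <- if (inherits(fit, "scale_fit")) fit$s else fit
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0) {
    abort("scale must be a single positive number.")
  }
  out <- list(pairs = NULL, records = NULL)
  if (!is.null(pairs)) {
    pairs <- as_tibble(pairs)
    pairs$epsilon_original <- pairs$epsilon
    pairs$epsilon <- pairs$epsilon * s
    out$pairs <- pairs
  }
  if (!is.null(records)) {
    records <- as_tibble(records)
    if (!"dh_att_model" %in% names(records)) {
      abort("`records` is missing column(s): dh_att_model.")
    }
    records$dh_att_updated <- s * records$dh_att_model
    if ("dg_cavity" %in% names(records)) {
      records$dg_pred <- predict_hydration(records$dg_cavity,
                                           records$dh_att_updated)
    }
    out$records <- records
  }
  out
}

#' Derive the experiment-side reparameterization columns
#'
#' Adds `dh_att_exp = dg_hyd_exp - dg_cavity` to a hydration table, the
#' quantity the scale fit targets.
#'
#' @param records Data frame with `dg_hyd_exp` and `dg_cavity`.
#' @return The tibble with a `dh_att_exp` column.
#' @export
reparam_records <- function(records) {
  need <- setdiff(c("dg_hyd_exp", "dg_cavity"), names(records))
  if (length(need) > 0) {
    abort(paste0("`records` is missing column(s): ",
                 paste(need, collapse = ", "), "."))
  }
  records <- as_tibble(records)
  records$dh_att_exp <- attraction_from_decomposition(records$dg_hyd_exp,
                                                      records$dg_cavity)
  records
}

#' Full reparameterization report for one water model
#'
#' Drives the whole cavity-decomposition procedure on a hydration table:
#' derives the experiment-side attraction enthalpies, fits the global scale,
#' rescales the model enthalpies and the cross-pair well depths, and predicts
#' the post-update hydration free energies. This reproduces, for the packaged
#' SPC/E data, the published per-alkane table and updated-epsilon table.
#'
#' @param records Hydration table with columns `n_carbons`, `dg_hyd_exp`,
#'   `dg_cavity`, `dh_att_model` (missing model cells are allowed and
#'   propagate as `NA`).
#' @param pairs Optional cross-pair tibble (e.g. [cross_pairs()]) to rescale.
#' @param method Scale-fit method, see [fit_global_scale()].
#' @return A list of class `reparam_report`: `records` (all derived columns),
#'   `pairs` (updated epsilons, when supplied), `fit` (the `scale_fit`).
#' @examples
#' rep <- build_reparam_table(load_reference(), cross_pairs("spce"))
#' rep$records[, c("n_carbons", "dh_att_updated", "dg_pred")]
#' @export
build_reparam_table <- function(records, pairs = NULL,
                                method = c("mean_ratio", "weighted_ls")) {
  method <- match.arg(method)
  records <- reparam_records(records)
  if (!"dh_att_model" %in% names(records)) {
    abort("`records` is missing column(s): dh_att_model.")
  }
  fit <- fit_global_scale(records, method)
  scaled <- apply_scale(fit, pairs = pairs, records = records)
  structure(list(records = scaled$records, pairs = scaled$pairs, fit = fit),
            class = "reparam_report")
}

#' @export
print.reparam_report <- function(x, ...) {
  print(x$fit)
  cat("\nPer-alkane table:\n")
  print(x$records, n = Inf)
  if (!is.null(x$pairs)) {
    cat("\nUpdated cross pairs:\n")
    print(x$pairs)
  }
  invisible(x)
}

#' @export
tidy.reparam_report <- function(x, ...) x$records

#' @export
glance.reparam_report <- function(x, ...) glance(x$fit)
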