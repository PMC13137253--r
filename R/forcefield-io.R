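ff_dir <- function() system.file("extdata", "forcefield", package = "hydralk")

#' Shipped force-field parameter sets
#'
#' `list_forcefields()` names the parameter files shipped with the package;
#' `read_forcefield()` parses one into a site tibble. Files are flat YAML with
#' a `sites:` list; each site carries `sigma_nm` and either `epsilon_kJmol`
#' or `epsilon_over_kB_K` (converted with the package's Boltzmann constant).
#' The `hh_alkane` file is pair-level (`pairs:` with cross well depths and a
#' null sigma) and is returned with an `NA` sigma column.
#'
#' @param model Model name (one of `list_forcefields()`) or a path to a
#'   YAML file with the same schema.
#' @return A tibble with columns `name`, `epsilon` (kJ/mol), `sigma` (nm)
#'   plus, for pair-level files, `epsilon_updated`. The model name and kind
#'   are attached as attributes `model` and `kind`.
#' @examples
#' read_forcefield("trappe_ua")
#' read_forcefield("spce")
#' @export
read_forcefield <- function(model) {
  path <- if (file.exists(model)) model else
    file.path(ff_dir(), paste0(model, ".yaml"))
  if (!file.exists(path)) {
    abort(paste0("Unknown force field `", model, "`. Available: ",
                 paste(list_forcefields(), collapse = ", "), "."))
  }
  doc <- yaml::read_yaml(path)
  entries <- doc$sites %||% doc$pairs
  if (is.null(entries)) abort("Force-field file has neither `sites:` nor `pairs:`.")
  rows <- purrr::map_dfr(entries, function(s) {
    eps <- if (!is.null(s$epsilon_kJmol)) s$epsilon_kJmol
           else if (!is.null(s$epsilon_over_kB_K)) s$epsilon_over_kB_K * kB_kJ_mol_K
           else abort(paste0("Site `", s$name,
                             "` needs epsilon_kJmol or epsilon_over_kB_K."))
    tibble(
      name = s$name,
      epsilon = eps,
      sigma = if (is.null(s$sigma_nm)) NA_real_ else s$sigma_nm,
      epsilon_updated = if (is.null(s$epsilon_updated_kJmol)) NA_real_
                        else s$epsilon_updated_kJmol
    )
  })
  if (all(is.na(rows$epsilon_updated))) rows$epsilon_updated <- NULL
  if (any(rows$epsilon < 0) || any(!is.na(rows$sigma) & rows$sigma <= 0)) {
    abort("Invalid parameters in force-field file (epsilon < 0 or sigma <= 0).")
  }
  structure(rows, model = doc$model, kind = doc$kind)
}

#' @rdname read_forcefield
#' @export
list_forcefields <- function() {
  sub("\\.yaml$", "", list.files(ff_dir(), pattern = "\\.yaml$"))
}

#' Alkane-water cross parameters for a water model
#'
#' Convenience wrapper: mixes the TraPPE-UA united-atom sites with the O site
#' of the requested water model under Lorentz-Berthelot.
#'
#' @param water_model One of `"spce"`, `"opc3"`, `"tip4p2005"`, `"opc"`.
#' @param alkane Alkane parameter set name, default `"trappe_ua"`.
#' @return Tibble of cross pairs (`name`, `epsilon`, `sigma`, `origin`).
#' @examples
#' cross_pairs("spce") # CH4:O epsilon = 0.8942 kJ/mol
#' @export
cross_pairs <- function(water_model, alkane = "trappe_ua") {
  sites <- read_forcefield(alkane)
  water <- read_forcefield(water_model)
  if (!identical(attr(water, "kind"), "water")) {
    abort(paste0("`", water_model, "` is not a water parameter set."))
  }
  out <- mix_pairs(sites, water[1, ])
  out$name <- paste0(out$name, ":O")
  out
}
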