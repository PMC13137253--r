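# md5 of the shipped reference file; guards against silent fixture edits
.reference_md5 <- c(
  spce_hydration = "677fa75a573f0d63f5fbfeeea25ade4c"
)

#' Packaged hydration reference data
#'
#' Loads the packaged per-alkane hydration table for TraPPE-UA + SPC/E:
#' experimental (or, beyond octane, group-contribution) hydration free
#' energies, the simulated hydration free energies of the unmodified model,
#' cavity-formation free energies taken from earlier cavity studies, and the
#' model attraction enthalpies. All energies in kJ/mol at 300 K. Rows with a
#' missing post-update simulation value are carried as `NA`, never imputed.
#'
#' The file's md5 checksum is pinned; a mismatch is a hard error, since every
#' downstream reparameterization number flows from this table.
#'
#' @param name Reference set name; currently `"spce_hydration"`.
#' @return Tibble with columns `n_carbons`, `dg_hyd_exp`, `dg_hyd_model`,
#'   `dg_cavity`, `dh_att_model`, `dg_hyd_sim`, `provenance`.
#' @examples
#' ref <- load_reference()
#' ref[ref$n_carbons == 1, ] # methane: 8.37, cavity 24.52
#' @export
load_reference <- function(name = "spce_hydration") {
  if (!name %in% names(.reference_md5)) {
    abort(paste0("Unknown reference set `", name, "`."))
  }
  path <- system.file("extdata", "reference",
                      paste0(if (name == "spce_hydration") "spce_hydration_reference"
                             else name, ".csv"),
                      package = "hydralk")
  sum_got <- unname(tools::md5sum(path))
  if (!identical(sum_got, unname(.reference_md5[name]))) {
    abort(paste0("Reference fixture `", name, "` failed its checksum (got ",
                 sum_got, "); refusing to use a modified fixture."))
  }
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    n_carbons = readr::col_integer(),
                    provenance = readr::col_character(),
                    .default = readr::col_double()
                  ))
}
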