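#' Plot a per-window free-energy profile
#'
#' Window increments against the coupling parameter; the area under the
#' steps is the accumulated free energy.
#'
#' @param object A `fep_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fep_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$lam_i + .data$lam_j) / 2,
                                   y = .data$dg)) +
    ggplot2::geom_col(width = abs(df$lam_j[1] - df$lam_i[1]) * 0.9,
                      fill = "steelblue") +
    ggplot2::labs(x = expression(lambda),
                  y = expression(Delta * g[i] ~ "(kJ/mol)"),
                  title = paste0("Per-window increments (", object$direction,
                                 "), total = ",
                                 format(object$total, digits = 4),
                                 " kJ/mol")) +
    ggplot2::theme_minimal()
}

#' Plot a radial distribution function
#'
#' @param object An `rdf_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rdf_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$r, .data$g)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "r (nm)", y = "g(r)") +
    ggplot2::theme_minimal()
}

#' Predicted versus reference hydration free energies
#'
#' Per-alkane comparison of the post-update predictions with the
#' experimental / group-contribution values driving the fit.
#'
#' @param report A `reparam_report` from [build_reparam_table()].
#' @return A ggplot object.
#' @export
plot_reparam <- function(report) {
  stopifnot(inherits(report, "reparam_report"))
  df <- report$records |>
    tidyr::pivot_longer(dplyr::any_of(c("dg_hyd_exp", "dg_hyd_model",
                                        "dg_pred")),
                        names_to = "series", values_to = "dg")
  labels <- c(dg_hyd_exp = "experiment / group contribution",
              dg_hyd_model = "original model", dg_pred = "predicted (updated)")
  ggplot2::ggplot(df, ggplot2::aes(.data$n_carbons, .data$dg,
                                   colour = labels[.data$series],
                                   shape = labels[.data$series])) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "carbon number", y = expression(Delta * G[hyd] ~ "(kJ/mol)"),
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
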