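#' Convert energies to thermal (kT) units
#'
#' Dimensionless free energies `dG / (kB T)` with per-temperature
#' normalisation; `from_kt()` is the exact inverse.
#'
#' @param dg Energy in kJ/mol (vectorised).
#' @param x Dimensionless energy in kT units.
#' @param temperature Temperature in K (vectorised).
#' @return Numeric vector.
#' @examples
#' to_kt(kT(300), 300) # exactly 1
#' @export
to_kt <- function(dg, temperature) dg / kT(temperature)

#' @rdname to_kt
#' @export
from_kt <- function(x, temperature) x * kT(temperature)

#' RMSD between a model series and a reference series
#'
#' Root mean squared deviation over a shared temperature grid; the grids
#' must match exactly (no interpolation is attempted).
#'
#' @param model,ref Data frames with columns `T_K` and `value` (any common
#'   unit; use [to_kt()] first for kT-unit RMSDs).
#' @return The RMSD, in the unit of `value`.
#' @export
rmsd_vs_reference <- function(model, ref) {
  for (df in list(model, ref)) {
    if (!all(c("T_K", "value") %in% names(df))) {
      abort("series need columns `T_K` and `value`.")
    }
  }
  if (nrow(model) != nrow(ref) ||
      any(abs(sort(model$T_K) - sort(ref$T_K)) > 1e-9)) {
    abort("temperature grids do not match; supply both series on one grid.")
  }
  m <- model[order(model$T_K), ]
  r <- ref[order(ref$T_K), ]
  sqrt(mean((m$value - r$value)^2))
}

#' Temperature dependence of the hydration free energy
#'
#' The standard excess-thermodynamics form
#'
#'   `dG(T) = dG(T0) + (C_ex - S_ex)(T - T0) - C_ex T ln(T / T0)`
#'
#' with excess entropy `S_ex` (at `T0`) and excess heat capacity `C_ex`
#' treated as temperature-independent. `eval_thermo_fit()` evaluates it;
#' `fit_thermo_curve()` estimates the three parameters. The model is linear
#' in `(dG(T0), S_ex, C_ex)`, so the fit is an ordinary least-squares
#' problem solved by QR; no starting values are needed. On a narrow
#' temperature range the two non-constant regressors are nearly collinear
#' and the fit is ill-conditioned - the design-matrix condition number is
#' reported and a warning is raised above `kappa_warn`.
#'
#' @param data Data frame with columns `T_K` and `dg` (kJ/mol), at least 3
#'   distinct temperatures.
#' @param T0 Reference temperature, K.
#' @param kappa_warn Condition-number threshold for the ill-conditioning
#'   warning.
#' @return Object of class `thermo_fit` with elements `dg_T0`, `S_ex`,
#'   `C_ex` (kJ/(mol K)), `T0`, `residuals`, `kappa`. Supports [tidy()] and
#'   [glance()].
#' @examples
#' Tg <- seq(250, 400, by = 10)
#' dg <- eval_thermo_fit(Tg, dg_T0 = 8.4, S_ex = -0.05, C_ex = 0.0012, T0 = 300)
#' fit_thermo_curve(data.frame(T_K = Tg, dg = dg))
#' @export
fit_thermo_curve <- function(data, T0 = 300, kappa_warn = 1000) {
  if (!all(c("T_K", "dg") %in% names(data))) {
    abort("`data` needs columns `T_K` and `dg`.")
  }
  if (length(unique(data$T_K)) < 3L) {
    abort("need at least 3 distinct temperatures to fit 3 parameters.")
  }
  tt <- data$T_K
  # dg = a - S_ex (T - T0) + C_ex [ (T - T0) - T ln(T/T0) ]
  x1 <- -(tt - T0)
  x2 <- (tt - T0) - tt * log(tt / T0)
  fit <- lm(data$dg ~ x1 + x2)
  kap <- kappa(stats::model.matrix(fit), exact = TRUE)
  if (kap > kappa_warn) {
    warn(paste0("thermodynamic fit is ill-conditioned (condition number ",
                format(kap, digits = 3),
                "); a narrow temperature range cannot separate S_ex and C_ex."))
  }
  cf <- coef(fit)
  structure(list(dg_T0 = unname(cf[1]), S_ex = unname(cf[2]),
                 C_ex = unname(cf[3]), T0 = T0,
                 residuals = unname(stats::residuals(fit)), kappa = kap),
            class = "thermo_fit")
}

#' @rdname fit_thermo_curve
#' @param T_K Temperatures at which to evaluate, K.
#' @param dg_T0,S_ex,C_ex,T0 Model parameters (kJ/mol, kJ/(mol K),
#'   kJ/(mol K), K).
#' @export
eval_thermo_fit <- function(T_K, dg_T0, S_ex, C_ex, T0 = 300) {
  dg_T0 + (C_ex - S_ex) * (T_K - T0) - C_ex * T_K * log(T_K / T0)
}

#' @export
print.thermo_fit <- function(x, ...) {
  cat("Hydration free-energy temperature fit (T0 = ", x$T0, " K)\n",
      "  dG(T0) = ", format(x$dg_T0, digits = 6), " kJ/mol\n",
      "  S_ex   = ", format(x$S_ex, digits = 6), " kJ/(mol K)\n",
      "  C_ex   = ", format(x$C_ex, digits = 6), " kJ/(mol K)\n",
      "  condition number ", format(x$kappa, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.thermo_fit <- function(x, ...) {
  tibble(term = c("dg_T0", "S_ex", "C_ex"),
         estimate = c(x$dg_T0, x$S_ex, x$C_ex),
         unit = c("kJ/mol", "kJ/(mol K)", "kJ/(mol K)"))
}

#' @export
glance.thermo_fit <- function(x, ...) {
  tibble(dg_T0 = x$dg_T0, S_ex = x$S_ex, C_ex = x$C_ex, T0 = x$T0,
         kappa = x$kappa, rmse = sqrt(mean(x$residuals^2)),
         n = length(x$residuals))
}
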