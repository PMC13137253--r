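#' Uniform lambda-window schedule
#'
#' The coupling parameter runs from 0 (decoupled solute) to 1 (fully
#' coupled) in `1/delta` equal windows; the default spacing 0.025 gives the
#' standard 40-window protocol.
#'
#' @param delta Window spacing; `1/delta` must be an integer (to 1e-9).
#' @return Tibble with one row per window: `window`, `lam_i`, `lam_j`.
#' @examples
#' nrow(lambda_schedule())      # 40
#' lambda_schedule(0.5)$lam_j   # 0.5, 1
#' @export
lambda_schedule <- function(delta = 0.025) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta <= 0 || delta > 1) {
    abort("`delta` must be a single number in (0, 1].")
  }
  n <- 1 / delta
  if (abs(n - round(n)) > 1e-9) {
    abort(paste0("`delta` = ", delta, " does not divide [0, 1] evenly; ",
                 "choose a spacing whose reciprocal is an integer ",
                 "(e.g. 0.025, 0.05, 0.1)."))
  }
  n <- as.integer(round(n))
  values <- seq(0, 1, length.out = n + 1L)
  tibble(window = seq_len(n), lam_i = values[-(n + 1L)], lam_j = values[-1L])
}

#' One-window free-energy increment (volume-weighted exponential average)
#'
#' The NPT perturbation estimator for one window:
#'
#'   `dg = -kT * ln( <V exp(-dU/kT)> / <V> )`
#'
#' with `dU = U(lam_j) - U(lam_i)` and both averages over configurations
#' sampled at `lam_i`. When all volumes are equal this reduces exactly to the
#' plain exponential (Zwanzig) average. The exponential is evaluated
#' log-sum-exp stabilised (max shift before exponentiation), so overflow
#' cannot occur for any finite `dU`.
#'
#' @param dU Energy gaps `U(lam_j) - U(lam_i)` in kJ/mol at sampled
#'   configurations.
#' @param V Box volumes (nm^3) at the same configurations; `NULL` means
#'   constant volume.
#' @param temperature Temperature in K.
#' @return The window increment in kJ/mol.
#' @examples
#' window_increment(rep(2.5, 100), temperature = 300) # constant gap: 2.5
#' @export
window_increment <- function(dU, V = NULL, temperature = 300) {
  if (length(dU) < 1L) abort("`dU` must contain at least one sample.")
  if (any(!is.finite(dU))) abort("`dU` must be finite.")
  if (is.null(V)) V <- rep(1, length(dU))
  if (length(V) != length(dU)) abort("`dU` and `V` must have equal length.")
  if (any(!is.finite(V)) || any(V <= 0)) abort("`V` must be finite and > 0.")
  kt <- kT(temperature)
  x <- -dU / kt
  m <- max(x)
  # log( sum(V e^x) / sum(V) ) with the max shifted out
  log_ratio <- m + log(sum(V * exp(x - m))) - log(sum(V))
  -kt * log_ratio
}

#' Accumulate window increments into a free-energy estimate
#'
#' Sums the per-window increments over an ordered, gap-free chain of
#' adjacent windows. Forward chains (lambda increasing, 0 -> 1) estimate the
#' hydration (coupling) free energy; reverse chains (1 -> 0) its negative.
#'
#' @param samples Long-format tibble of window samples with columns `lam_i`,
#'   `lam_j`, `dU` and optionally `V` (as produced by [mc_run()] or
#'   [gaussian_gap_samples()], or read with [read_window_samples()]).
#' @param temperature Temperature in K.
#' @return Object of class `fep_result`: per-window tibble, `total` (kJ/mol),
#'   `direction`, `temperature`. Supports [tidy()], [glance()], [autoplot()].
#' @export
fep_accumulate <- function(samples, temperature = 300) {
  need <- setdiff(c("lam_i", "lam_j", "dU"), names(samples))
  if (length(need) > 0) {
    abort(paste0("`samples` is missing column(s): ",
                 paste(need, collapse = ", "), "."))
  }
  if (!"V" %in% names(samples)) samples$V <- 1
  wins <- dplyr::distinct(samples[, c("lam_i", "lam_j")])
  if (nrow(wins) == 0) abort("`samples` is empty.")
  dir_sign <- sign(wins$lam_j - wins$lam_i)
  if (any(dir_sign == 0) || length(unique(dir_sign)) != 1L) {
    abort("windows must all run in one direction (lam_j != lam_i, same sign).")
  }
  direction <- if (dir_sign[1] > 0) "forward" else "reverse"
  wins <- wins[order(wins$lam_i, decreasing = direction == "reverse"), ]
  if (nrow(wins) > 1L &&
      any(abs(wins$lam_i[-1L] - wins$lam_j[-nrow(wins)]) > 1e-9)) {
    abort("lambda windows have a gap or overlap; they must chain end to end.")
  }
  per_window <- samples |>
    dplyr::group_by(.data$lam_i, .data$lam_j) |>
    dplyr::summarise(
      dg = window_increment(.data$dU, .data$V, temperature),
      n_samples = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(if (direction == "forward") .data$lam_i else -.data$lam_i)
  structure(
    list(per_window = per_window, total = sum(per_window$dg),
         direction = direction, temperature = temperature),
    class = "fep_result")
}

#' @export
print.fep_result <- function(x, ...) {
  cat("FEP estimate (", x$direction, ", ", nrow(x$per_window), " windows, T = ",
      x$temperature, " K)\n  total = ", format(x$total, digits = 5),
      " kJ/mol\n", sep = "")
  invisible(x)
}

#' @export
tidy.fep_result <- function(x, ...) x$per_window

#' @export
glance.fep_result <- function(x, ...) {
  tibble(total = x$total, n_windows = nrow(x$per_window),
         direction = x$direction, temperature = x$temperature)
}

#' Forward/reverse closure (hysteresis) of a perturbation path
#'
#' A forward (0 -> 1) and a reverse (1 -> 0) estimate of the same coupling
#' path should sum to zero up to sampling error; the signed sum is the
#' standard internal-consistency diagnostic.
#'
#' @param fwd,rev `fep_result` objects of opposite direction at the same
#'   temperature.
#' @return Signed closure error `fwd$total + rev$total` in kJ/mol.
#' @export
fep_hysteresis <- function(fwd, rev) {
  if (!inherits(fwd, "fep_result") || !inherits(rev, "fep_result")) {
    abort("inputs must be `fep_result` objects.")
  }
  if (identical(fwd$direction, rev$direction)) {
    abort("`fwd` and `rev` must have opposite directions.")
  }
  if (!isTRUE(all.equal(fwd$temperature, rev$temperature))) {
    abort("`fwd` and `rev` must share a temperature.")
  }
  fwd$total + rev$total
}

#' Replicate mean and spread
#'
#' Mean and sample standard deviation (n - 1 denominator) over independent
#' replicate totals, the uncertainty convention used throughout the package.
#'
#' @param totals Numeric vector of replicate estimates (length >= 2).
#' @return Tibble with `mean`, `sd`, `n`.
#' @examples
#' replicate_stats(c(1, 3)) # mean 2, sd sqrt(2)
#' @export
replicate_stats <- function(totals) {
  if (length(totals) < 2L) abort("need at least 2 replicates.")
  if (any(!is.finite(totals))) abort("`totals` must be finite.")
  tibble(mean = mean(totals), sd = sd(totals), n = length(totals))
}

#' Read and write window samples as TSV
#'
#' Plain-text interchange for per-window samples so the estimator can consume
#' externally produced data: columns `lam_i`, `lam_j`, `dU_kJmol`, `V_nm3`,
#' one sampled configuration per row.
#'
#' @param path File path.
#' @param samples Tibble with `lam_i`, `lam_j`, `dU` and optionally `V`.
#' @return `read_window_samples()` returns the samples tibble (columns
#'   `lam_i`, `lam_j`, `dU`, `V`); `write_window_samples()` returns `path`
#'   invisibly.
#' @export
read_window_samples <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  need <- setdiff(c("lam_i", "lam_j", "dU_kJmol"), names(df))
  if (length(need) > 0) {
    abort(paste0("window-sample file is missing column(s): ",
                 paste(need, collapse = ", "), "."))
  }
  tibble(lam_i = df$lam_i, lam_j = df$lam_j, dU = df$dU_kJmol,
         V = if ("V_nm3" %in% names(df)) df$V_nm3 else 1)
}

#' @rdname read_window_samples
#' @export
write_window_samples <- function(samples, path) {
  out <- tibble(lam_i = samples$lam_i, lam_j = samples$lam_j,
                dU_kJmol = samples$dU,
                V_nm3 = if ("V" %in% names(samples)) samples$V else 1)
  readr::write_tsv(out, path)
  invisible(path)
}
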