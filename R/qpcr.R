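#' Exponential qPCR standard curve
#'
#' Calibration of the form `amount = A * exp(-k * Ct)`, the exponential
#' re-expression of the usual linear Ct versus log10(amount) regression.
#' The reference calibration used throughout the package is
#' `amount = 2922 * exp(-0.71 * Ct)`.
#'
#' @param A prefactor in amount units (> 0): the amount giving Ct = 0.
#' @param k decay constant per cycle (> 0).
#' @param r_squared optional R^2 of the Ct-vs-log10(amount) fit.
#' @return an object of class `standard_curve`.
#' @seealso [fit_standard_curve()], [curve_slope_and_efficiency()]
#' @export
standard_curve <- function(A, k, r_squared = NA_real_) {
  assert_scalar_num(A, "A", lower = 0, strict_lower = TRUE)
  assert_scalar_num(k, "k", lower = 0, strict_lower = TRUE)
  structure(list(A = A, k = k, r_squared = r_squared),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  eff <- curve_slope_and_efficiency(x)
  cat(sprintf("qPCR standard curve: amount = %.4g * exp(-%.4g * Ct)\n", x$A, x$k))
  cat(sprintf("  slope (Ct vs log10 amount): %.4g\n", eff$slope))
  cat(sprintf("  amplification efficiency:   %.1f%%\n", eff$efficiency_percent))
  if (is.finite(x$r_squared)) cat(sprintf("  R^2: %.4g\n", x$r_squared))
  invisible(x)
}

#' Fit a qPCR standard curve from a dilution series
#'
#' Regresses Ct on log(amount) — the instrument-software convention, so the
#' quoted slope refers to the Ct versus log10(amount) plot — and re-expresses
#' the line as the exponential calibration `amount = A * exp(-k * Ct)`.
#'
#' @param table data.frame with columns `amount` (> 0) and `ct`; at least 3
#'   distinct amounts are required.
#' @return a [standard_curve()] with `r_squared` from the Ct-vs-log10(amount)
#'   regression.
#' @examples
#' tab <- gen_qpcr_dilution_series(standard_curve(2922, 0.71),
#'                                 amounts = 10^(0:9), noise_sd_ct = 0, seed = 1)
#' fit_standard_curve(tab)
#' @export
fit_standard_curve <- function(table) {
  stopifnot(is.data.frame(table), all(c("amount", "ct") %in% names(table)))
  if (any(table$amount <= 0)) stop("amounts must be > 0", call. = FALSE)
  if (length(unique(table$amount)) < 3)
    stop("need >= 3 distinct amounts", call. = FALSE)
  fit <- stats::lm(ct ~ log10(amount), data = table)
  m <- unname(stats::coef(fit)[2])          # slope in Ct per log10(amount)
  b <- unname(stats::coef(fit)[1])
  if (m >= 0) stop("Ct must decrease with amount; check the table", call. = FALSE)
  # Ct = b + m*log10(x)  =>  x = 10^((Ct - b)/m) = A * exp(-k*Ct)
  k <- -log(10) / m
  A <- 10^(-b / m)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((table$ct - mean(table$ct))^2)
  standard_curve(A, k, r_squared = r2)
}

#' Slope and amplification efficiency of a standard curve
#'
#' The Ct-vs-log10(amount) slope is `m = -ln(10)/k`; the per-cycle
#' amplification efficiency is `E = 10^(-1/m) - 1` (100% for perfect
#' doubling, i.e. m = -1/log10(2) = -3.32).
#'
#' @param curve a [standard_curve()].
#' @return list with `slope` and `efficiency_percent`.
#' @examples
#' curve_slope_and_efficiency(standard_curve(2922, 0.71))
#' @export
curve_slope_and_efficiency <- function(curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$k <= 0) stop("k must be > 0", call. = FALSE)
  m <- -log(10) / curve$k
  list(slope = m, efficiency_percent = 100 * (10^(-1 / m) - 1))
}

#' Convert a Ct value to a DNA amount
#'
#' @param ct threshold cycle (finite numeric, vectorized). `NA` Ct values
#'   (no amplification within the run) propagate as `NA` amounts: treat them
#'   as below the detection limit at the maximum cycle number.
#' @param curve a [standard_curve()].
#' @param dilution_factor fold-dilution of the template before qPCR (the
#'   returned amount is scaled back up by this factor), default 1.
#' @return numeric amount(s), `dilution_factor * A * exp(-k * ct)`.
#' @examples
#' quantify_amount(10, standard_curve(2922, 0.71))
#' @export
quantify_amount <- function(ct, curve, dilution_factor = 1) {
  stopifnot(inherits(curve, "standard_curve"))
  assert_scalar_num(dilution_factor, "dilution_factor", lower = 0,
                    strict_lower = TRUE)
  if (any(is.infinite(ct), na.rm = TRUE))
    stop("`ct` must be finite (use NA for no amplification)", call. = FALSE)
  dilution_factor * curve$A * exp(-curve$k * ct)
}

#' Invert a standard curve: amount to expected Ct
#'
#' @param amount DNA amount (> 0, vectorized).
#' @param curve a [standard_curve()].
#' @return expected Ct, `log(A / amount) / k`.
#' @export
invert_amount <- function(amount, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(amount <= 0)) stop("`amount` must be > 0", call. = FALSE)
  log(curve$A / amount) / curve$k
}

#' Assembly reaction efficiency
#'
#' Efficiency is the measured full-length product concentration divided by
#' the theoretical maximum: one full-length product per input oligo set,
#' i.e. the limiting per-oligo concentration.
#'
#' @param product_conc measured product concentration (> 0 allowed to be 0
#'   for undetectable product).
#' @param per_oligo_initial_conc initial concentration of each oligo, in the
#'   same units; when oligos are supplied at unequal concentrations pass the
#'   limiting (minimum) one, or a vector whose minimum is used.
#' @return efficiency in \[0, 1\].
#' @examples
#' reaction_efficiency(1.2e-15, 5.0e-9)  # 1.2 fM product from 5 nM oligos
#' @export
reaction_efficiency <- function(product_conc, per_oligo_initial_conc) {
  assert_scalar_num(product_conc, "product_conc", lower = 0)
  theo <- min(per_oligo_initial_conc)
  if (!is.finite(theo) || theo <= 0)
    stop("`per_oligo_initial_conc` must be > 0", call. = FALSE)
  eta <- product_conc / theo
  if (eta > 1)
    stop("efficiency > 1: product exceeds the theoretical maximum; ",
         "inputs are inconsistent", call. = FALSE)
  eta
}

#' Droplet-vs-control enhancement factor
#'
#' Ratio of the condensate-enhanced assembly efficiency to the control
#' (no-droplet) efficiency. When the control is undetectable (efficiency 0)
#' no finite factor exists and a distinguished outcome is returned.
#'
#' @param eta_droplet,eta_control reaction efficiencies (>= 0).
#' @return list with `factor` (numeric, or `NA` when undetectable) and
#'   `control_undetectable` (logical).
#' @examples
#' enhancement_factor(0.0114, 0.0005)
#' enhancement_factor(0.01, 0)$control_undetectable
#' @export
enhancement_factor <- function(eta_droplet, eta_control) {
  assert_scalar_num(eta_droplet, "eta_droplet", lower = 0)
  assert_scalar_num(eta_control, "eta_control", lower = 0)
  if (eta_control == 0)
    return(list(factor = NA_real_, control_undetectable = TRUE))
  list(factor = eta_droplet / eta_control, control_undetectable = FALSE)
}

#' Generate a synthetic qPCR dilution series
#'
#' Inverts the calibration at each amount and adds Gaussian noise to the Ct
#' values, emulating a serial-dilution standard run.
#'
#' @param curve a [standard_curve()] (the generating truth).
#' @param amounts positive amounts, e.g. `10^(0:9)` for ten 10-fold dilutions.
#' @param noise_sd_ct standard deviation of Gaussian Ct noise (>= 0).
#' @param seed integer seed.
#' @return data.frame with columns `amount` and `ct`.
#' @export
gen_qpcr_dilution_series <- function(curve, amounts, noise_sd_ct, seed) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(amounts <= 0)) stop("amounts must be > 0", call. = FALSE)
  assert_scalar_num(noise_sd_ct, "noise_sd_ct", lower = 0)
  ct <- invert_amount(amounts, curve)
  if (noise_sd_ct > 0)
    ct <- ct + with_local_seed(seed, stats::rnorm(length(ct), 0, noise_sd_ct))
  data.frame(amount = amounts, ct = ct)
}
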