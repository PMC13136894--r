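#' Fit a single-exponential lifetime to a photon decay histogram (tail fit)
#'
#' Tail-fits a single-exponential decay model to a time-correlated
#' single-photon-counting histogram: bins after the histogram peak (offset by
#' `tail_start_fraction` of the post-peak window, to clear the instrument
#' rise) are fitted by weighted least squares of log-counts versus time, with
#' weights proportional to counts — the standard linearization in which the
#' count weighting approximates Poisson errors on the log scale.
#'
#' @param decay data.frame with columns `time_ns` and `counts`.
#' @param tail_start_fraction fraction of the post-peak window skipped before
#'   the fit starts (default 0.05).
#' @return list of class `flim_fit` with `tau` (ns), `amplitude`, `window`
#'   (first/last bin index used), `reduced_chisq` (Poisson residual statistic;
#'   values well above ~1.5 flag non-single-exponential decays) and
#'   `n_bins_used`.
#' @examples
#' h <- gen_flim_decay(2.5, 1e6, 0.08, 256, seed = 1)
#' fit_flim_lifetime(h)$tau
#' @export
fit_flim_lifetime <- function(decay, tail_start_fraction = 0.05) {
  stopifnot(is.data.frame(decay), all(c("time_ns", "counts") %in% names(decay)))
  assert_scalar_num(tail_start_fraction, "tail_start_fraction", 0, 0.9)
  n <- nrow(decay)
  peak <- which.max(decay$counts)
  start <- min(n, peak + max(1L, round(tail_start_fraction * (n - peak))))
  window <- start:n
  use <- window[decay$counts[window] > 0]
  if (length(use) < 5)
    stop("need >= 5 nonzero bins in the tail window", call. = FALSE)
  t <- decay$time_ns[use]
  y <- decay$counts[use]
  fit <- stats::lm(log(y) ~ t, weights = y)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) stop("tail is not decaying; cannot fit a lifetime", call. = FALSE)
  tau <- -1 / slope
  amplitude <- exp(unname(stats::coef(fit)[1]))
  fitted_counts <- amplitude * exp(-t / tau)
  red_chisq <- sum((y - fitted_counts)^2 / fitted_counts) / (length(use) - 2)
  structure(list(tau = tau, amplitude = amplitude,
                 window = c(start = start, end = n),
                 reduced_chisq = red_chisq, n_bins_used = length(use)),
            class = "flim_fit")
}

#' Lifetime-based quantum-yield correction of a partition coefficient
#'
#' Intensity-based PCs conflate concentration with quantum yield; when the
#' dye's lifetime differs between the condensed and dilute phases, the
#' quantum yield is taken as proportional to the lifetime, so the intensity
#' measured inside is de-rated by `tau_out / tau_in`:
#' `PC_corrected = PC_raw * tau_out / tau_in`.
#'
#' @param pc_raw raw intensity-ratio partition coefficient (> 0).
#' @param tau_in,tau_out lifetimes (ns) inside and outside droplets (> 0).
#' @return corrected partition coefficient.
#' @examples
#' flim_correct_pc(100, tau_in = 4, tau_out = 3.2)  # 80
#' @export
flim_correct_pc <- function(pc_raw, tau_in, tau_out) {
  if (any(pc_raw <= 0)) stop("`pc_raw` must be > 0", call. = FALSE)
  assert_scalar_num(tau_in, "tau_in", lower = 0, strict_lower = TRUE)
  assert_scalar_num(tau_out, "tau_out", lower = 0, strict_lower = TRUE)
  pc_raw * tau_out / tau_in
}
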