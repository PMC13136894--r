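#' Ratiometric FRET efficiency
#'
#' Computes `E = F_A / (F_A + gamma * F_D)` from sensitized-emission
#' (acceptor) and donor channel intensities, where `gamma` corrects for the
#' detection-efficiency and quantum-yield imbalance between the two channels.
#'
#' @param f_a acceptor (FRET) channel intensity (>= 0, vectorized).
#' @param f_d donor channel intensity (>= 0, vectorized).
#' @param gamma correction factor (> 0), default 1.
#' @return FRET efficiency in \[0, 1\].
#' @examples
#' fret_efficiency(84.9, 15.1, gamma = 1)
#' @export
fret_efficiency <- function(f_a, f_d, gamma = 1) {
  if (any(f_a < 0) || any(f_d < 0))
    stop("intensities must be >= 0", call. = FALSE)
  assert_scalar_num(gamma, "gamma", lower = 0, strict_lower = TRUE)
  if (any(f_a + f_d == 0))
    stop("F_A and F_D are both 0: FRET efficiency undefined", call. = FALSE)
  f_a / (f_a + gamma * f_d)
}

#' Calibrate the FRET gamma factor from a reference construct
#'
#' Given intensity pairs measured on a reference of known FRET efficiency
#' (e.g. a double-labelled zero-length donor-acceptor control), finds the
#' gamma for which the mean computed efficiency equals the reference value.
#' The mean efficiency is strictly decreasing in gamma, so the root is
#' unique.
#'
#' @param f_a,f_d paired channel intensities of the reference measurements
#'   (`f_d` must be positive).
#' @param e_reference known efficiency of the reference, in (0, 1).
#' @return the calibrated gamma.
#' @examples
#' estimate_gamma(f_a = 60, f_d = 60, e_reference = 0.5)  # 1
#' @export
estimate_gamma <- function(f_a, f_d, e_reference) {
  assert_scalar_num(e_reference, "e_reference", lower = 0, upper = 1)
  if (e_reference <= 0 || e_reference >= 1)
    stop("`e_reference` must be in (0, 1)", call. = FALSE)
  stopifnot(length(f_a) == length(f_d))
  if (any(f_d <= 0)) stop("reference `f_d` must be > 0", call. = FALSE)
  if (any(f_a < 0)) stop("`f_a` must be >= 0", call. = FALSE)
  obj <- function(g) mean(f_a / (f_a + g * f_d)) - e_reference
  lo <- 1e-6; hi <- 1e6
  if (obj(lo) < 0 || obj(hi) > 0)
    stop("no gamma in (1e-6, 1e6) reproduces `e_reference`", call. = FALSE)
  stats::uniroot(obj, c(lo, hi), tol = 1e-12)$root
}
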