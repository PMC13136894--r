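#' Run an expression under a local RNG seed
#'
#' Evaluates `expr` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so generators never leak randomness into the caller's
#' session. All stochastic functions in the package route their randomness
#' through this helper; a call with the same seed is bit-reproducible.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials (> 0).
#' @param conf confidence level, default 0.95.
#' @return named numeric vector with `estimate`, `lower`, `upper`.
#' @examples
#' wilson_ci(5, 1000)
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # at the boundaries centre - half is exactly 0 (or centre + half exactly 1);
  # pin them so floating-point dust never excludes a true boundary value
  lower <- if (x == 0) 0 else max(0, centre - half)
  upper <- if (x == n) 1 else min(1, centre + half)
  c(estimate = p, lower = lower, upper = upper)
}

# scalar validators used across constructors
assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("`%s` must be > %s", name, lower), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("`%s` must be >= %s", name, lower), call. = FALSE)
  if (x > upper)
    stop(sprintf("`%s` must be <= %s", name, upper), call. = FALSE)
  invisible(x)
}
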