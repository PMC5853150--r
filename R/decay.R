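#' Single-exponential decay curve
#'
#' Expected black-carbon area at time `t` under the one-compartment clearance
#' model \eqn{R_0 e^{-kt}}. `k` may be negative, in which case the curve grows
#' (net accumulation rather than net clearance).
#'
#' @param R0 Initial area in square micrometres (non-negative).
#' @param k Decay constant in 1/day (any sign).
#' @param t Time in days.
#' @return Expected area in square micrometres, recycled over the longest
#'   argument.
#' @examples
#' decay_curve(1.122, 0.013, c(0, 53.3, 106.6))
#' @export
decay_curve <- function(R0, k, t) {
  if (any(R0 < 0, na.rm = TRUE)) {
    stop("R0 must be non-negative", call. = FALSE)
  }
  R0 * exp(-k * t)
}

#' Clearance half-life
#'
#' \eqn{t_{1/2} = \ln(2)/k} for a positive decay constant. A zero or negative
#' `k` means no net clearance; the half-life is then `Inf`.
#'
#' @param k Decay constant in 1/day.
#' @return Half-life in days; `Inf` where `k <= 0`.
#' @examples
#' half_life(0.013) # ~53 days
#' half_life(0.006) # ~116 days
#' @export
half_life <- function(k) {
  out <- ifelse(k > 0, log(2) / k, Inf)
  # keep names/shape of input
  attributes(out) <- attributes(k)
  out
}

#' Credible interval for the half-life from a k interval
#'
#' The map k -> ln(2)/k is monotone decreasing on k > 0, so the half-life
#' interval bounds are ln(2)/k_upper and ln(2)/k_lower. If the lower k bound
#' is not positive the upper half-life bound is `Inf` (no net clearance cannot
#' be excluded).
#'
#' @param k_lower,k_upper Lower and upper bounds of the k credible interval.
#' @return Named numeric vector with elements `lower` and `upper` (days).
#' @examples
#' half_life_interval(0.007, 0.023) # c(30.1, 99.0)
#' @export
half_life_interval <- function(k_lower, k_upper) {
  stopifnot(length(k_lower) == 1L, length(k_upper) == 1L)
  if (k_upper < k_lower) stop("interval bounds out of order", call. = FALSE)
  c(lower = half_life(k_upper), upper = half_life(k_lower))
}
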