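#' Noise-induced drift of the stochastic growth law
#'
#' Effective drift of the one-dimensional Fokker–Planck equation obtained
#' from the Stratonovich model with correlated multiplicative (on the
#' negative-feedback rate) and additive white noises:
#' \deqn{A(x) = f(x) + D(\delta+1)x^{2\delta+1} -
#'   \lambda\sqrt{DQ}(\delta+1)x^\delta,}
#' where `f` is the deterministic [apr()]. With `D = Q = 0` the drift reduces
#' to `f` exactly.
#'
#' @inheritParams rpr
#' @param noise A [noise_params()] triple.
#' @return Drift values, same length as `x`.
#' @export
drift_A <- function(params, noise, x) {
  assert_growth_params(params)
  assert_noise_params(noise)
  if (any(!is.finite(x)) || any(x <= 0))
    abort("drift_A: `x` must be finite and > 0")
  d <- params$delta
  apr(params, x) + noise$D * (d + 1) * x^(2 * d + 1) -
    noise$lambda * sqrt(noise$D * noise$Q) * (d + 1) * x^d
}

#' Noise-induced diffusion coefficient
#'
#' \deqn{B(x) = D x^{2\delta+2} - 2\lambda\sqrt{DQ}\, x^{\delta+1} + Q.}
#' Nonnegative for all `x >= 0` and `|lambda| <= 1` (it is bounded below by
#' \eqn{(1-|\lambda|)(Dx^{2\delta+2} + Q)}); for `lambda = 1` it is the
#' perfect square \eqn{(\sqrt{D}x^{\delta+1} - \sqrt{Q})^2}, which vanishes
#' at \eqn{x = (Q/D)^{1/(2\delta+2)}}.
#'
#' @inheritParams drift_A
#' @param x Scaled density, `>= 0`. Vectorised.
#' @return Nonnegative diffusion values.
#' @export
diffusion_B <- function(params, noise, x) {
  assert_growth_params(params)
  assert_noise_params(noise)
  if (any(!is.finite(x)) || any(x < 0))
    abort("diffusion_B: `x` must be finite and >= 0")
  d <- params$delta
  noise$D * x^(2 * d + 2) -
    2 * noise$lambda * sqrt(noise$D * noise$Q) * x^(d + 1) + noise$Q
}

# dB/dx, used by the extrema condition A(x) - B'(x) = 0.
diffusion_B_deriv <- function(params, noise, x) {
  d <- params$delta
  noise$D * (2 * d + 2) * x^(2 * d + 1) -
    2 * noise$lambda * sqrt(noise$D * noise$Q) * (d + 1) * x^d
}

#' First-order stochastic approximation of the conditional MSSCD
#'
#' Expansion of the stationary-density extremum condition about the carrying
#' capacity gives
#' \deqn{x^* \approx K - K\frac{nK^{\delta+1} + D(\delta+1)K^{2\delta+1} -
#'   \lambda\sqrt{DQ}(\delta+1)K^\delta}
#'   {\beta r_p K^{\alpha+1} + n(\delta+1)K^{\delta+1} +
#'    D(\delta+1)(2\delta+1)K^{2\delta+1} -
#'    \lambda\sqrt{DQ}\,\delta(\delta+1)K^\delta},}
#' the conditional MSSCD under correlated noise; for `alpha == delta` the
#' same expression specialises to the printed equal-regulator variant. The
#' accompanying second-order condition is evaluated at the returned value
#' with the cross-noise coefficient taken as \eqn{\lambda\sqrt{DQ}} (the
#' dimensionally consistent form; it matches the equal-regulator variant).
#' The value increases with additive noise strength `Q` and decreases with
#' multiplicative strength `D` at `lambda = 1`.
#'
#' @inheritParams drift_A
#' @return One-row tibble with `value`, `condition_met` (logical: the
#'   second-order concavity condition holds at `value`), and `degenerate`
#'   (TRUE with `value = NA` when the denominator vanishes).
#' @export
mssd_stochastic_approx <- function(params, noise) {
  assert_growth_params(params)
  assert_noise_params(noise)
  K <- params$K; d <- params$delta
  cdq <- noise$lambda * sqrt(noise$D * noise$Q)
  num <- params$n * K^(d + 1) + noise$D * (d + 1) * K^(2 * d + 1) -
    cdq * (d + 1) * K^d
  den <- params$beta * params$r_p * K^(params$alpha + 1) +
    params$n * (d + 1) * K^(d + 1) +
    noise$D * (d + 1) * (2 * d + 1) * K^(2 * d + 1) -
    cdq * d * (d + 1) * K^d
  if (den == 0)
    return(tibble(value = NA_real_, condition_met = NA, degenerate = TRUE))
  xs <- K - K * num / den
  cond <- if (xs > 0) {
    with(params,
         r_p * (alpha + 1) * xs^alpha -
           (r_p / K^beta) * (alpha + beta + 1) * xs^(alpha + beta) -
           n * (d + 1) * xs^d) -
      noise$D * (d + 1) * (2 * d + 1) * xs^(2 * d) +
      cdq * d * (d + 1) * xs^(d - 1) < 0
  } else NA
  tibble(value = xs, condition_met = cond, degenerate = FALSE)
}
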