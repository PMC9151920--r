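#' Absolute proliferation rate (APR)
#'
#' Right-hand side of the extended logistic growth law,
#' \deqn{f(x) = r_p x^{\alpha+1}(1 - (x/K)^\beta) - n x^{\delta+1}.}
#' Both terms carry positive powers of `x`, so `apr(params, 0) == 0` for any
#' valid hexad, and at the carrying capacity the crowding bracket vanishes so
#' `apr(params, K) == -n * K^(delta + 1)` exactly.
#'
#' @param params A [growth_params()] hexad.
#' @param x Scaled cell density, `>= 0`. Vectorised.
#' @return Proliferation rate in density per hour, same length as `x`.
#' @seealso [rpr()], [apr_deriv()], [find_equilibria()]
#' @export
apr <- function(params, x) {
  assert_growth_params(params)
  if (any(!is.finite(x)) || any(x < 0))
    abort("apr: `x` must be finite and >= 0 (fractional powers are undefined for negative density)")
  with(params,
       r_p * x^(alpha + 1) * (1 - (x / K)^beta) - n * x^(delta + 1))
}

#' Relative proliferation rate (RPR)
#'
#' The per-capita rate \eqn{f(x)/x = r_p x^\alpha (1 - (x/K)^\beta) - n x^\delta}.
#' Unlike the plain logistic, this law can be negative at small positive
#' densities (a strong-Allee-like regime): below the conditional threshold
#' density the population decays.
#'
#' @inheritParams apr
#' @param x Scaled cell density, strictly `> 0`. Vectorised.
#' @return Per-hour rate, same length as `x`; may be negative.
#' @export
rpr <- function(params, x) {
  assert_growth_params(params)
  if (any(!is.finite(x)) || any(x <= 0))
    abort("rpr: `x` must be finite and > 0")
  with(params, r_p * x^alpha * (1 - (x / K)^beta) - n * x^delta)
}

#' Derivative of the absolute proliferation rate
#'
#' Closed-form \eqn{f'(x) = r_p(\alpha+1)x^\alpha -
#' r_p(\alpha+\beta+1)x^{\alpha+\beta}/K^\beta - n(\delta+1)x^\delta}, used for
#' stability classification and inflection points of the density profile. For
#' `delta < 1` the derivative is unbounded or undefined at `x = 0`, hence the
#' strictly positive domain.
#'
#' @inheritParams rpr
#' @return Rate derivative (per hour), same length as `x`.
#' @export
apr_deriv <- function(params, x) {
  assert_growth_params(params)
  if (any(!is.finite(x)) || any(x <= 0))
    abort("apr_deriv: `x` must be finite and > 0")
  with(params,
       r_p * (alpha + 1) * x^alpha -
         (r_p * (alpha + beta + 1) / K^beta) * x^(alpha + beta) -
         n * (delta + 1) * x^delta)
}

#' Deterministic potential of the growth law
#'
#' \eqn{U(x) = -\int_0^x f(u)\,du}, i.e.
#' \deqn{U(x) = -\left[\frac{r_p x^{\alpha+2}}{\alpha+2}
#'   - \frac{r_p}{K^\beta}\frac{x^{\alpha+\beta+2}}{\alpha+\beta+2}
#'   - \frac{n x^{\delta+2}}{\delta+2}\right].}
#' Local minima of `U` sit at stable equilibria (the deepest accessible well
#' at the maximum sustainable stable cell density, MSSCD), the interior local
#' maximum at the threshold density. `U(0) = 0` by construction.
#'
#' @inheritParams apr
#' @return Potential values, same length as `x`.
#' @export
potential <- function(params, x) {
  assert_growth_params(params)
  if (any(!is.finite(x)) || any(x < 0))
    abort("potential: `x` must be finite and >= 0")
  with(params,
       -(r_p * x^(alpha + 2) / (alpha + 2) -
           (r_p / K^beta) * x^(alpha + beta + 2) / (alpha + beta + 2) -
           n * x^(delta + 2) / (delta + 2)))
}
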