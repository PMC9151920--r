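#' Parameter hexad of the extended logistic growth law
#'
#' The growth law is
#' \deqn{\frac{dx}{dt} = r_p\, x^{\alpha+1}\left(1 - (x/K)^\beta\right) - n\, x^{\delta+1},}
#' where the intrinsic proliferation rate is density dependent
#' (\eqn{r = r_p x^\alpha}, with \eqn{\alpha} regulating cell-cell
#' cooperation), \eqn{\beta} is the allometric exponent of the crowding /
#' environmental-resistance term \eqn{(x/K)^\beta}, and \eqn{n x^{\delta+1}}
#' is density-regulated negative feedback from growth-inhibiting molecules
#' (e.g. penicillin or streptomycin in the culture medium), distinct from
#' contact inhibition.
#'
#' @param r_p Constant intrinsic proliferation rate (per hour), `> 0`.
#' @param K Carrying capacity in scaled density units, `> 0`.
#' @param n Negative-feedback rate coefficient (per hour), `>= 0`.
#' @param alpha Cooperation regulator exponent (dimensionless), `>= 0`.
#' @param beta Crowding / environmental-resistance exponent, `> 0`.
#' @param delta Growth-inhibitor interaction regulator exponent, `>= 0`.
#'
#' @return An object of class `growth_params`: a named list of the six
#'   parameters.
#'
#' @examples
#' p <- growth_params(r_p = 0.13, K = 1.43, n = 0.0095,
#'                    alpha = 1.15, beta = 0.99, delta = 0.2)
#' apr(p, 0.5)
#' @export
growth_params <- function(r_p, K, n = 0, alpha = 0, beta = 1, delta = 0) {
  vals <- list(r_p = r_p, K = K, n = n, alpha = alpha, beta = beta,
               delta = delta)
  bad <- names(vals)[!vapply(vals, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v), logical(1))]
  if (length(bad))
    abort(paste0("growth_params: non-finite or non-scalar value for ",
                 paste(bad, collapse = ", ")))
  if (r_p <= 0) abort("growth_params: `r_p` must be > 0")
  if (K <= 0) abort("growth_params: `K` must be > 0")
  if (n < 0) abort("growth_params: `n` must be >= 0")
  if (alpha < 0) abort("growth_params: `alpha` must be >= 0")
  if (beta <= 0) abort("growth_params: `beta` must be > 0")
  if (delta < 0) abort("growth_params: `delta` must be >= 0")
  structure(lapply(vals, as.numeric), class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat("<growth_params>\n")
  cat(sprintf("  r_p = %g (per h)   K = %g   n = %g (per h)\n",
              x$r_p, x$K, x$n))
  cat(sprintf("  alpha = %g   beta = %g   delta = %g\n",
              x$alpha, x$beta, x$delta))
  invisible(x)
}

#' @export
as.list.growth_params <- function(x, ...) unclass(x)

#' Coerce a flat named list or vector to a growth parameter hexad
#'
#' Accepts the flat key-value serialisation with keys
#' `r_p, K, n, alpha, beta, delta` (extra keys are ignored).
#'
#' @param x Named list or named numeric vector.
#' @return A [growth_params()] object.
#' @export
as_growth_params <- function(x) {
  if (inherits(x, "growth_params")) return(x)
  x <- as.list(x)
  need <- c("r_p", "K", "n", "alpha", "beta", "delta")
  miss <- setdiff(need, names(x))
  if (length(miss))
    abort(paste0("as_growth_params: missing keys: ",
                 paste(miss, collapse = ", ")))
  do.call(growth_params, lapply(x[need], as.numeric))
}

#' @export
tidy.growth_params <- function(x, ...) {
  tibble(term = names(unclass(x)), estimate = unlist(unclass(x), use.names = FALSE))
}

#' Correlated-noise parameters for the stochastic growth law
#'
#' The stochastic analog perturbs the negative-feedback rate with
#' multiplicative Gaussian white noise of strength `D` and adds additive
#' Gaussian white noise of strength `Q`; the two noises are delta-correlated
#' with correlation strength `lambda`
#' (\eqn{\langle \varepsilon(t)\Gamma(t') \rangle = 2\lambda\sqrt{DQ}\,\delta(t-t')}).
#'
#' @param D Multiplicative noise strength, `>= 0`. Grows with heterogeneity
#'   of the growth-inhibiting molecules in the culture medium.
#' @param Q Additive noise strength, `>= 0`. Grows with environmental
#'   fluctuation of the culture setup.
#' @param lambda Correlation strength between the two noises, in `[-1, 1]`.
#'
#' @return An object of class `noise_params`. `D = Q = 0` is legal and
#'   recovers the deterministic model.
#' @export
noise_params <- function(D = 0, Q = 0, lambda = 0) {
  vals <- list(D = D, Q = Q, lambda = lambda)
  bad <- names(vals)[!vapply(vals, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v), logical(1))]
  if (length(bad))
    abort(paste0("noise_params: non-finite or non-scalar value for ",
                 paste(bad, collapse = ", ")))
  if (D < 0) abort("noise_params: `D` must be >= 0")
  if (Q < 0) abort("noise_params: `Q` must be >= 0")
  if (abs(lambda) > 1) abort("noise_params: `lambda` must lie in [-1, 1]")
  structure(lapply(vals, as.numeric), class = "noise_params")
}

#' @export
print.noise_params <- function(x, ...) {
  cat(sprintf("<noise_params> D = %g, Q = %g, lambda = %g\n",
              x$D, x$Q, x$lambda))
  invisible(x)
}

assert_growth_params <- function(params) {
  if (!inherits(params, "growth_params"))
    abort("`params` must be a growth_params object (see growth_params())")
  invisible(params)
}

assert_noise_params <- function(noise) {
  if (!inherits(noise, "noise_params"))
    abort("`noise` must be a noise_params object (see noise_params())")
  invisible(noise)
}
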