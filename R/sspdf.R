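#' Stationary probability density of the stochastic growth law
#'
#' Closed-form steady state of the Fokker–Planck equation
#' \eqn{\partial_t P = -\partial_x[A P] + \partial_x^2[B P]}:
#' \deqn{P_{st}(x) = \frac{N'}{B(x)}
#'   \exp\left(\int^x \frac{A(u)}{B(u)}\,du\right),}
#' normalised so the density integrates to one on `(0, x_max]` (the infinite
#' upper limit is truncated; `x_max` is raised automatically until the tail
#' value is below `1e-10` of the peak). The log-density is accumulated by
#' trapezoid quadrature of `A/B` and exponentiated stably by subtracting the
#' running maximum.
#'
#' For `|lambda| = 1` the diffusion `B` has an interior zero when
#' `(Q/D)^{1/(2 delta + 2)} <= x_max`; the quadrature then uses
#' `B + 1e-12 * max(Q, D)` and the result is flagged `regularized`.
#'
#' @inheritParams drift_A
#' @param x_max Truncation bound of the density grid (default `3 * K`,
#'   auto-raised as needed).
#' @param n_grid Number of grid points.
#' @return A tibble of class `sspdf` with columns `density` and `pdf`, and
#'   attributes `x_max`, `normalization_residual`, `regularized`, `params`,
#'   `noise`.
#'
#' @examples
#' p <- growth_params(0.13, 1.43, 0.0095, 1.15, 0.99, 0.2)
#' s <- stationary_pdf(p, noise_params(D = 0.002, Q = 0.06, lambda = 0.4))
#' s$density[which.max(s$pdf)]
#' @export
stationary_pdf <- function(params, noise, x_max = NULL, n_grid = 8001L) {
  assert_growth_params(params)
  assert_noise_params(noise)
  if (noise$D + noise$Q <= 0)
    abort("stationary_pdf: need D + Q > 0 (deterministic limit has no density)")
  xm <- x_max %||% (3 * params$K)
  auto <- is.null(x_max)
  for (rep in 1:12) {
    grid <- seq(xm / n_grid, xm, length.out = n_grid)
    B <- diffusion_B(params, noise, grid)
    # |lambda| = 1 makes B a perfect square with an interior zero at
    # (Q/D)^(1/(2 delta + 2)); regularise the quadrature there
    reg <- abs(noise$lambda) == 1 && noise$D > 0 && noise$Q > 0 &&
      (noise$Q / noise$D)^(1 / (2 * params$delta + 2)) <= xm
    if (reg) B <- B + 1e-12 * max(noise$Q, noise$D)
    if (min(B) <= 0)
      abort("stationary_pdf: diffusion vanished on the grid; check parameters")
    A <- drift_A(params, noise, grid)
    logP <- -log(B) + as.numeric(pracma::cumtrapz(grid, A / B))
    P <- exp(logP - max(logP))
    Z <- pracma::trapz(grid, P)
    P <- P / Z
    if (!auto || P[n_grid] < 1e-10 * max(P)) break
    xm <- xm * 1.5
  }
  resid <- abs(1 - pracma::trapz(grid, P))
  structure(tibble(density = grid, pdf = P),
            class = c("sspdf", class(tibble())),
            x_max = xm, normalization_residual = resid,
            regularized = reg, params = params, noise = noise)
}

#' @export
print.sspdf <- function(x, ...) {
  cat(sprintf(
    "Stationary density on (0, %.4g], mode at %.4g%s\n",
    attr(x, "x_max"), x$density[which.max(x$pdf)],
    if (attr(x, "regularized")) " (diffusion regularized)" else ""))
  NextMethod()
  invisible(x)
}

#' Stationary probability flux of a computed density
#'
#' \eqn{J(x) = A(x)P(x) - \frac{d}{dx}[B(x)P(x)]}, evaluated with central
#' finite differences on the interior grid. The closed-form stationary
#' density makes `J` vanish identically, so the sup-norm of the returned
#' flux (relative to `max |A P|`) is a numerical-quality diagnostic. For
#' fractional exponents the drift's derivatives are unbounded at the origin,
#' where central differences lose their nominal order, so the diagnostic
#' skips a thin boundary layer (densities below `boundary_frac` of `x_max`).
#'
#' @param sspdf A result of [stationary_pdf()].
#' @param boundary_frac Fraction of `x_max` excluded at the lower end.
#' @return A tibble with columns `density` and `flux` (interior grid only).
#' @export
stationary_flux <- function(sspdf, boundary_frac = 0.002) {
  if (!inherits(sspdf, "sspdf"))
    abort("stationary_flux: `sspdf` must come from stationary_pdf()")
  params <- attr(sspdf, "params"); noise <- attr(sspdf, "noise")
  x <- sspdf$density; P <- sspdf$pdf
  BP <- diffusion_B(params, noise, x) * P
  m <- length(x)
  i <- 2:(m - 1)
  dBP <- (BP[i + 1] - BP[i - 1]) / (x[i + 1] - x[i - 1])
  out <- tibble(density = x[i],
                flux = drift_A(params, noise, x[i]) * P[i] - dBP)
  out[out$density > boundary_frac * attr(sspdf, "x_max"), ]
}

#' Extrema of the stationary density
#'
#' The stationary density has \eqn{dP_{st}/dx = 0} exactly where
#' \eqn{A(x) - B'(x) = 0}; this solves that condition with the same
#' bracket-and-bisect engine as [find_equilibria()]. In the small-noise
#' limit the roots approach the nonzero deterministic equilibria.
#'
#' @inheritParams drift_A
#' @param x_max Upper end of the root search, default `3 * K`.
#' @return Ascending numeric vector of densities (possibly empty).
#' @export
sspdf_extrema <- function(params, noise, x_max = 3 * params$K) {
  assert_growth_params(params)
  assert_noise_params(noise)
  root_scan(function(x) drift_A(params, noise, x) -
              diffusion_B_deriv(params, noise, x),
            upper = x_max, scale = params$K)
}
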