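#' Integrate the deterministic growth law
#'
#' Solves \eqn{dx/dt = f(x)} from `x0` at the requested time points with an
#' adaptive solver (deSolve, `lsoda`, rtol `1e-9`, atol `1e-12`); the state
#' is clipped at 0 from below inside the right-hand side so fractional
#' exponents stay defined. Initial densities above the conditional threshold
#' converge to the MSSCD, those below it decay to extinction.
#'
#' @inheritParams apr
#' @param x0 Initial scaled density, `>= 0`.
#' @param times Strictly increasing time grid in hours (the first entry is
#'   the time of `x0`).
#' @param rtol,atol Solver tolerances.
#' @return A tibble with columns `time_h` and `density`.
#'
#' @examples
#' p <- growth_params(0.13, 1.43, 0.0095, 1.15, 0.99, 0.2)
#' tr <- solve_trajectory(p, x0 = 0.1, times = seq(0, 48, by = 2))
#' tail(tr)
#' @export
solve_trajectory <- function(params, x0, times, rtol = 1e-9, atol = 1e-12) {
  assert_growth_params(params)
  if (!is.numeric(x0) || length(x0) != 1L || !is.finite(x0) || x0 < 0)
    abort("solve_trajectory: `x0` must be a finite scalar >= 0")
  if (length(times) < 2L || any(diff(times) <= 0))
    abort("solve_trajectory: `times` must be strictly increasing, length >= 2")
  rhs <- function(t, y, parms) list(apr(params, max(y, 0)))
  sol <- deSolve::ode(y = c(x = x0), times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (nrow(sol) < length(times)) {
    last <- sol[nrow(sol), ]
    abort(sprintf(
      "solve_trajectory: solver stopped at t = %g with density %g",
      last[[1]], last[[2]]))
  }
  tibble(time_h = as.numeric(sol[, "time"]),
         density = pmax(as.numeric(sol[, "x"]), 0))
}
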