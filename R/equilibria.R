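# Shared bracket-and-bisect root engine.
#
# Scans `f` on a composite grid over (lo, upper]: log-spaced points resolve
# roots far below K (the threshold density can be two orders of magnitude
# smaller than the carrying capacity), a linear sweep covers the rest. Every
# sign-change bracket is polished with uniroot to |dx| <= 1e-12 * scale.
root_scan <- function(f, upper, scale, lo = 1e-8 * scale, n_grid = 4000L) {
  xs <- sort(unique(c(
    exp(seq(log(lo), log(upper), length.out = n_grid %/% 2)),
    seq(lo, upper, length.out = n_grid %/% 2)
  )))
  fx <- f(xs)
  ok <- is.finite(fx)
  xs <- xs[ok]; fx <- fx[ok]
  roots <- numeric(0)
  sgn <- sign(fx)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in idx) {
    r <- uniroot(f, lower = xs[i], upper = xs[i + 1],
                 tol = 1e-12 * scale)$root
    roots <- c(roots, r)
  }
  # exact grid hits
  roots <- sort(unique(c(roots, xs[fx == 0])))
  # merge near-duplicates
  if (length(roots) > 1) {
    keep <- c(TRUE, diff(roots) > 1e-9 * scale)
    roots <- roots[keep]
  }
  roots
}

#' Equilibria and stability of the extended logistic growth law
#'
#' Finds all equilibria of \eqn{dx/dt = f(x)} on `[0, search_upper]` and
#' classifies their stability. `x = 0` is always an equilibrium; its
#' stability is read from the sign of `f` just above zero (for `delta < 1`
#' the law is not differentiable at the origin). Interior roots are located
#' by a composite log/linear bracket scan plus bisection and classified by
#' the sign of [apr_deriv()].
#'
#' With `n > 0` the typical structure is bistable: a stable equilibrium at 0,
#' an interior unstable *conditional threshold density* below which the
#' population decays, and a larger stable equilibrium — the *conditional
#' maximum sustainable stable cell density* (MSSCD), which sits below the
#' carrying capacity because of the negative feedback.
#'
#' @inheritParams apr
#' @param search_upper Upper bound of the root search, default `3 * K`
#'   (all interior equilibria lie below `K` when `n > 0`, since `f(K) < 0`).
#' @param n_grid Number of scan points in the bracket grid.
#'
#' @return A tibble of class `equilibrium_set` with columns `density`,
#'   `stability` (`"stable"`/`"unstable"`) and `method` (`"exact_zero"` or
#'   `"numeric_root"`), ordered by density, and attributes `threshold` and
#'   `mssd` (`NA` when absent).
#'
#' @examples
#' p <- growth_params(0.13, 1.43, 0.0095, 1.15, 0.99, 0.2)
#' eq <- find_equilibria(p)
#' eq
#' attr(eq, "mssd")
#' @export
find_equilibria <- function(params, search_upper = 3 * params$K,
                            n_grid = 4000L) {
  assert_growth_params(params)
  if (search_upper <= params$K)
    abort("find_equilibria: `search_upper` must exceed K")
  K <- params$K
  roots <- root_scan(function(x) apr(params, x), upper = search_upper,
                     scale = K, n_grid = n_grid)
  stab <- vapply(roots, function(r) {
    if (apr_deriv(params, r) < 0) "stable" else "unstable"
  }, character(1))
  zero_stab <- if (apr(params, 1e-6 * K) < 0) "stable" else "unstable"
  out <- tibble(
    density = c(0, roots),
    stability = c(zero_stab, stab),
    method = c("exact_zero", rep("numeric_root", length(roots)))
  )
  unst <- out$density[out$stability == "unstable" & out$density > 0]
  stbl <- out$density[out$stability == "stable" & out$density > 0]
  structure(out,
            class = c("equilibrium_set", class(out)),
            threshold = if (length(unst)) min(unst) else NA_real_,
            mssd = if (length(stbl)) max(stbl) else NA_real_)
}

#' @export
print.equilibrium_set <- function(x, ...) {
  cat("Equilibria of the extended logistic growth law\n")
  NextMethod()
  cat(sprintf("threshold = %s, mssd = %s\n",
              format(attr(x, "threshold")), format(attr(x, "mssd"))))
  invisible(x)
}

#' @export
glance.equilibrium_set <- function(x, ...) {
  tibble(n_equilibria = nrow(x),
         threshold = attr(x, "threshold"),
         mssd = attr(x, "mssd"))
}

# Quadratic-expansion pieces shared by the two closed-form branches:
# S = beta r_p K^alpha + n delta K^delta (first-order coefficient),
# H = 2 alpha beta r_p K^alpha + beta(beta-1) r_p K^alpha
#     + delta(delta-1) n K^delta (second-order coefficient),
# disc = S^2 - 2 H n K^delta.
theorem1_pieces <- function(params) {
  with(params, {
    S <- beta * r_p * K^alpha + n * delta * K^delta
    H <- 2 * alpha * beta * r_p * K^alpha +
      beta * (beta - 1) * r_p * K^alpha +
      delta * (delta - 1) * n * K^delta
    list(S = S, H = H, disc = S^2 - 2 * H * n * K^delta)
  })
}

#' Closed-form approximation of the MSSCD
#'
#' Second-order series expansion of the growth law about the carrying
#' capacity yields a quadratic whose minus-branch root approximates the
#' conditional maximum sustainable stable cell density:
#' \deqn{x^* \approx K - K\frac{S - \sqrt{S^2 - 2 H n K^\delta}}{H},}
#' with \eqn{S = \beta r_p K^\alpha + n\delta K^\delta} and
#' \eqn{H = 2\alpha\beta r_p K^\alpha + \beta(\beta-1) r_p K^\alpha +
#' \delta(\delta-1) n K^\delta}. When the discriminant is negative the
#' conditional MSSCD does not exist (returned with `exists = FALSE`, not an
#' error). With `n = 0` the value collapses to exactly `K`.
#'
#' The expansion is accurate near `K`; compare with the numeric root from
#' [find_equilibria()] when precision matters.
#'
#' @inheritParams apr
#' @return One-row tibble with columns `value` (NA when non-existent),
#'   `exists`, and `discriminant`.
#' @export
mssd_approx <- function(params) {
  assert_growth_params(params)
  pc <- theorem1_pieces(params)
  if (params$n == 0)
    return(tibble(value = params$K, exists = TRUE, discriminant = pc$disc))
  if (pc$disc < 0 || pc$H == 0)
    return(tibble(value = NA_real_, exists = FALSE, discriminant = pc$disc))
  tibble(value = params$K - params$K * (pc$S - sqrt(pc$disc)) / pc$H,
         exists = TRUE, discriminant = pc$disc)
}

#' Closed-form approximation of the conditional threshold density
#'
#' Plus-branch of the same quadratic expansion about `K` as [mssd_approx()].
#' Because the threshold typically lies far below the carrying capacity, the
#' expansion degrades there: for realistic hexads the branch value can be
#' several times the true root. The numeric root (from [find_equilibria()])
#' is therefore returned alongside so callers see the gap; prefer it for any
#' quantitative use.
#'
#' @inheritParams apr
#' @return One-row tibble with columns `value` (the branch formula),
#'   `numeric_root` (interior unstable equilibrium, NA if none), `exists`,
#'   and `discriminant`.
#' @export
threshold_approx <- function(params) {
  assert_growth_params(params)
  pc <- theorem1_pieces(params)
  num <- attr(find_equilibria(params), "threshold")
  if (pc$disc < 0 || pc$H == 0)
    return(tibble(value = NA_real_, numeric_root = num, exists = FALSE,
                  discriminant = pc$disc))
  tibble(value = params$K - params$K * (pc$S + sqrt(pc$disc)) / pc$H,
         numeric_root = num, exists = TRUE, discriminant = pc$disc)
}

#' Inflection densities of the growth curve
#'
#' All roots of \eqn{f'(x)} on the open interval up to the MSSCD (or `K` when
#' no interior stable equilibrium exists), in ascending order. At these
#' densities the absolute proliferation rate attains a local minimum /
#' maximum; the typical bistable configuration has two.
#'
#' @inheritParams apr
#' @return Ascending numeric vector (possibly of length < 2).
#' @export
inflection_densities <- function(params) {
  assert_growth_params(params)
  upper <- attr(find_equilibria(params), "mssd")
  if (is.na(upper)) upper <- params$K
  root_scan(function(x) apr_deriv(params, x), upper = upper,
            scale = params$K)
}

#' Density of maximum relative proliferation rate (numeric)
#'
#' Numerical argmax of [rpr()] on `(0, upper)`; the density at which the
#' per-capita rate peaks is a fitness measure for the proliferating
#' population.
#'
#' @inheritParams apr
#' @param upper Upper end of the search interval, default `K`.
#' @return The maximising density (scalar).
#' @export
max_rpr_density <- function(params, upper = params$K) {
  assert_growth_params(params)
  opt <- optimize(function(x) rpr(params, x), c(1e-9 * params$K, upper),
                  maximum = TRUE, tol = 1e-12)
  opt$maximum
}

#' Closed-form approximation of the maximum-RPR density
#'
#' First-order expansion about `K` gives
#' \deqn{x^* \approx K - K\frac{r_p\beta K^{\alpha-1} + n\delta K^{\delta-1}}
#' {2 r_p\alpha\beta K^{\alpha-1} + r_p\beta(\beta-1)K^{\alpha-1} +
#'  n\delta(\delta-1)K^{\delta-1}},}
#' valid for a concave-downward RPR profile; the concavity condition
#' \eqn{r_p\alpha(\alpha-1)x^{\alpha-2} -
#' (r_p/K^\beta)(\alpha+\beta)(\alpha+\beta-1)x^{\alpha+\beta-2} -
#' n\delta(\delta-1)x^{\delta-2} < 0} is evaluated at the returned value. For
#' `alpha == delta` the exact argmax is
#' \eqn{K\left(\alpha (r_p-n) / (r_p(\alpha+\beta))\right)^{1/\beta}};
#' compare with [max_rpr_density()] for the numeric answer.
#'
#' @inheritParams apr
#' @return One-row tibble with `value`, `concave_down` (logical), and
#'   `degenerate` (TRUE when the denominator vanishes; `value` is then NA).
#' @export
max_rpr_density_approx <- function(params) {
  assert_growth_params(params)
  den <- with(params,
              2 * r_p * alpha * beta * K^(alpha - 1) +
                r_p * beta * (beta - 1) * K^(alpha - 1) +
                n * delta * (delta - 1) * K^(delta - 1))
  num <- with(params, r_p * beta * K^(alpha - 1) + n * delta * K^(delta - 1))
  if (den == 0)
    return(tibble(value = NA_real_, concave_down = NA, degenerate = TRUE))
  xs <- params$K - params$K * num / den
  cc <- if (xs > 0) {
    with(params,
         r_p * alpha * (alpha - 1) * xs^(alpha - 2) -
           (r_p / K^beta) * (alpha + beta) * (alpha + beta - 1) *
           xs^(alpha + beta - 2) -
           n * delta * (delta - 1) * xs^(delta - 2)) < 0
  } else NA
  tibble(value = xs, concave_down = cc, degenerate = FALSE)
}
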