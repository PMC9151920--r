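#' Ensemble simulation of the stochastic growth law
#'
#' Integrates `n_paths` sample paths of the stochastic proliferation model
#' and records the terminal densities.
#'
#' Two schemes are available:
#' \describe{
#'   \item{`ito_em`}{(default) Euler–Maruyama on the Itô equation
#'     \eqn{dx = A(x)dt + \sqrt{2B(x)}\,dW} whose Fokker–Planck equation is
#'     exactly \eqn{\partial_t P = -\partial_x[AP] + \partial_x^2[BP]} — the
#'     convention behind [stationary_pdf()], so ensembles converge to that
#'     stationary density.}
#'   \item{`stratonovich_heun`}{Heun predictor–corrector on the original
#'     two-noise Stratonovich form
#'     \eqn{dx = f(x)dt - x^{\delta+1}\sqrt{2D}\circ dW_1 + \sqrt{2Q}\,dW_2}
#'     with correlated increments
#'     \eqn{dW_2 = \lambda dW_1 + \sqrt{1-\lambda^2}\,dW_3}. Statistically
#'     equivalent to the default at moderate `dt`; kept as a cross-check.}
#' }
#'
#' Two boundary treatments at zero are supported. The default is reflecting
#' (`x <- |x|` after each step): ensembles then converge to the stationary
#' Fokker–Planck density of [stationary_pdf()], which is normalised on the
#' positive axis. With `boundary = "absorbing"` a path that steps to zero or
#' below is extinct and stays at zero; the terminal mass at zero is then the
#' cumulative extinction probability up to `horizon` — a survival-analysis
#' reading under which noise-induced extinction modes are far more
#' pronounced than in the stationary occupancy. If more than 1% of all
#' path-steps reflect, the result is flagged (`reflect_warning`), a sign
#' that `dt` is too coarse for the chosen noise.
#'
#' @inheritParams drift_A
#' @param x0 Initial density for every path.
#' @param horizon Time horizon in hours (choose large enough to reach the
#'   steady state).
#' @param dt Step size in hours.
#' @param n_paths Number of sample paths.
#' @param seed Integer seed; results are fully reproducible given
#'   `(seed, dt, scheme)`.
#' @param scheme `"ito_em"` or `"stratonovich_heun"`.
#' @param boundary `"reflecting"` (default) or `"absorbing"` treatment of
#'   the zero-density boundary.
#' @return An object of class `growth_ensemble` with fields
#'   `final_densities`, `n_paths`, `horizon`, `dt`, `seed`, `scheme`,
#'   `reflect_frac`, `reflect_warning`, and the parameter objects.
#'
#' @examples
#' p <- growth_params(0.13, 1.43, 0.0095, 1.15, 0.99, 0.2)
#' en <- simulate_ensemble(p, noise_params(0.002, 0.06, 0.4), x0 = 0.1,
#'                         horizon = 30, dt = 0.01, n_paths = 50, seed = 1)
#' summary(en$final_densities)
#' @export
simulate_ensemble <- function(params, noise, x0, horizon, dt = 1e-3,
                              n_paths = 500L, seed,
                              scheme = c("ito_em", "stratonovich_heun"),
                              boundary = c("reflecting", "absorbing")) {
  assert_growth_params(params)
  assert_noise_params(noise)
  scheme <- match.arg(scheme)
  boundary <- match.arg(boundary)
  if (horizon <= 0 || dt <= 0) abort("simulate_ensemble: need horizon, dt > 0")
  if (n_paths < 1) abort("simulate_ensemble: need n_paths >= 1")
  if (missing(seed) || !is.numeric(seed))
    abort("simulate_ensemble: an explicit integer `seed` is required")
  set.seed(as.integer(seed))
  n_steps <- ceiling(horizon / dt)
  r_p <- params$r_p; K <- params$K; n <- params$n
  al <- params$alpha; be <- params$beta; de <- params$delta
  D <- noise$D; Q <- noise$Q
  cdq <- noise$lambda * sqrt(D * Q)
  x <- rep(as.numeric(x0), n_paths)
  n_reflect <- 0
  absorbing <- boundary == "absorbing"
  if (scheme == "ito_em") {
    sdt <- sqrt(dt)
    for (k in seq_len(n_steps)) {
      idx <- if (absorbing) which(x > 0) else seq_along(x)
      if (!length(idx)) break
      xa <- x[idx]
      xd <- xa^de
      xd1 <- xd * xa
      f <- r_p * xa^(al + 1) * (1 - (xa / K)^be) - n * xd1
      A <- f + D * (de + 1) * xd * xd1 - cdq * (de + 1) * xd
      B <- D * xd1 * xd1 - 2 * cdq * xd1 + Q
      xn <- xa + A * dt + sqrt(2 * pmax(B, 0)) * sdt * rnorm(length(idx))
      n_reflect <- n_reflect + sum(xn < 0)
      x[idx] <- if (absorbing) pmax(xn, 0) else abs(xn)
    }
  } else {
    s2d <- sqrt(2 * D); s2q <- sqrt(2 * Q)
    lam <- noise$lambda; sdt <- sqrt(dt)
    fdet <- function(x) {
      xd1 <- x^(de + 1)
      r_p * x^(al + 1) * (1 - (x / K)^be) - n * xd1
    }
    for (k in seq_len(n_steps)) {
      idx <- if (absorbing) which(x > 0) else seq_along(x)
      if (!length(idx)) break
      xa <- x[idx]
      dW1 <- sdt * rnorm(length(idx))
      dW2 <- lam * dW1 + sqrt(1 - lam^2) * sdt * rnorm(length(idx))
      b1 <- -s2d * xa^(de + 1)
      a0 <- fdet(xa)
      xp <- pmax(xa + a0 * dt + b1 * dW1 + s2q * dW2, 0)
      xn <- xa + 0.5 * (a0 + fdet(xp)) * dt +
        0.5 * (b1 - s2d * xp^(de + 1)) * dW1 + s2q * dW2
      n_reflect <- n_reflect + sum(xn < 0)
      x[idx] <- if (absorbing) pmax(xn, 0) else abs(xn)
    }
  }
  rf <- n_reflect / (n_paths * n_steps)
  structure(list(final_densities = x, n_paths = as.integer(n_paths),
                 horizon = horizon, dt = dt, seed = as.integer(seed),
                 scheme = scheme, boundary = boundary, reflect_frac = rf,
                 reflect_warning = boundary == "reflecting" && rf > 0.01,
                 params = params, noise = noise),
            class = "growth_ensemble")
}

#' @export
print.growth_ensemble <- function(x, ...) {
  cat(sprintf(
    "<growth_ensemble> %d paths, horizon %g h, dt %g h, scheme %s, seed %d\n",
    x$n_paths, x$horizon, x$dt, x$scheme, x$seed))
  cat(sprintf("  terminal density: median %.4g, IQR [%.4g, %.4g]%s\n",
              stats::median(x$final_densities),
              stats::quantile(x$final_densities, 0.25),
              stats::quantile(x$final_densities, 0.75),
              if (x$reflect_warning)
                sprintf(" (reflecting steps: %.1f%% - consider smaller dt)",
                        100 * x$reflect_frac) else ""))
  invisible(x)
}

#' @export
as_tibble.growth_ensemble <- function(x, ...) {
  tibble(path = seq_len(x$n_paths), final_density = x$final_densities)
}

# peak prominences for a count vector (histogram modality).
peak_prominence <- function(counts) {
  m <- length(counts)
  is_peak <- vapply(seq_len(m), function(i) {
    l <- if (i > 1) counts[i - 1] else -Inf
    r <- if (i < m) counts[i + 1] else -Inf
    counts[i] >= l && counts[i] >= r && (counts[i] > l || counts[i] > r)
  }, logical(1))
  if (m == 1L) is_peak <- counts > 0
  peaks <- which(is_peak)
  prom <- vapply(peaks, function(p) {
    h <- counts[p]
    side_col <- function(idx) {
      if (!length(idx)) return(min(counts[counts <= h], 0))
      higher <- idx[counts[idx] > h]
      span <- if (length(higher)) {
        nearest <- if (all(idx < p)) max(higher) else min(higher)
        if (all(idx < p)) seq(nearest, p) else seq(p, nearest)
      } else c(idx, p)
      min(counts[span])
    }
    l <- side_col(seq_len(p - 1))
    r <- side_col(if (p < m) seq(p + 1, m) else integer(0))
    h - max(l, r)
  }, numeric(1))
  list(peaks = peaks, prominence = prom)
}

#' Classify the steady-state mode structure of an ensemble
#'
#' Histograms the terminal densities with Freedman–Diaconis bins for the
#' surviving mass plus a dedicated extinction bin `[0, cutoff)`, then reads
#' off modality from local-maximum prominence. Under correlated noise the
#' stationary distribution ranges from unimodal near the conditional MSSCD
#' (high correlation, weak multiplicative noise) through bimodal (weak
#' correlation: extinction mode plus proliferation mode) to a single
#' extinction mode (strong multiplicative noise).
#'
#' @param ensemble A [simulate_ensemble()] result with at least 100 paths.
#' @param extinction_cutoff Density below which a path counts as extinct;
#'   defaults to `0.05 * K`.
#' @param prominence_frac Minimum peak prominence, as a fraction of the
#'   tallest bin, for a mode to be reported.
#' @return An object of class `mode_report`: list with `modality`
#'   (`"unimodal"`, `"bimodal"`, or `"degenerate"`), `modes` (tibble of
#'   `location`, `count`, `prominence`, `extinction_bin`; at most two, by
#'   prominence), and `extinction_mass`.
#' @export
classify_steady_state <- function(ensemble, extinction_cutoff = NULL,
                                  prominence_frac = 0.05) {
  if (!inherits(ensemble, "growth_ensemble"))
    abort("classify_steady_state: `ensemble` must come from simulate_ensemble()")
  if (ensemble$n_paths < 100)
    abort("classify_steady_state: need at least 100 paths")
  cutoff <- extinction_cutoff %||% (0.05 * ensemble$params$K)
  xs <- ensemble$final_densities
  ext_mass <- mean(xs < cutoff)
  surv <- xs[xs >= cutoff]
  if (length(surv) >= 2 && stats::sd(surv) > 0) {
    bw <- 2 * stats::IQR(surv) / length(surv)^(1 / 3)
    if (bw <= 0) bw <- diff(range(surv)) / 10
    breaks <- seq(cutoff, max(surv) + bw, by = bw)
    h <- graphics::hist(surv, breaks = breaks, plot = FALSE)
    counts <- c(sum(xs < cutoff), h$counts)
    centers <- c(cutoff / 2, h$mids)
  } else {
    counts <- c(sum(xs < cutoff), length(surv))
    centers <- c(cutoff / 2, if (length(surv)) mean(surv) else cutoff)
  }
  pk <- peak_prominence(counts)
  # peaks must clear both a relative floor and a Poisson-noise floor
  keep <- pk$prominence >= prominence_frac * max(counts) &
    pk$prominence >= 3 * sqrt(pmax(counts[pk$peaks], 1)) &
    counts[pk$peaks] > 0
  modes <- tibble(bin = pk$peaks[keep],
                  location = centers[pk$peaks[keep]],
                  count = counts[pk$peaks[keep]],
                  prominence = pk$prominence[keep],
                  extinction_bin = pk$peaks[keep] == 1L) |>
    dplyr::arrange(.data$bin)
  # merge peaks separated by a shallow valley (sampling noise on one bump)
  while (nrow(modes) > 1L) {
    merged <- FALSE
    for (i in seq_len(nrow(modes) - 1L)) {
      valley <- min(counts[seq(modes$bin[i], modes$bin[i + 1L])])
      if (valley > 0.5 * min(modes$count[i], modes$count[i + 1L])) {
        drop <- if (modes$count[i] < modes$count[i + 1L]) i else i + 1L
        modes <- modes[-drop, ]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  modes <- modes |> dplyr::arrange(dplyr::desc(.data$prominence)) |>
    head(2L) |> dplyr::arrange(.data$location) |>
    dplyr::select(-"bin")
  modality <- if (nrow(modes) == 0L) "degenerate"
  else if (nrow(modes) == 1L) "unimodal" else "bimodal"
  structure(list(modality = modality, modes = modes,
                 extinction_mass = ext_mass, extinction_cutoff = cutoff),
            class = "mode_report")
}

#' @export
print.mode_report <- function(x, ...) {
  cat(sprintf("<mode_report> %s; extinction mass %.3f (cutoff %.3g)\n",
              x$modality, x$extinction_mass, x$extinction_cutoff))
  print(x$modes)
  invisible(x)
}

#' @export
tidy.mode_report <- function(x, ...) x$modes

#' @export
glance.mode_report <- function(x, ...) {
  tibble(modality = x$modality, n_modes = nrow(x$modes),
         extinction_mass = x$extinction_mass)
}
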