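#' Fisher RGR profile of a density time series
#'
#' Converts replicated density-vs-time observations into a density–RPR
#' profile using Fisher's relative growth rate estimator on the
#' replicate-mean series: for each consecutive pair of observations,
#' \deqn{RPR_i = \frac{\ln \bar x_{i+1} - \ln \bar x_i}{t_{i+1} - t_i},}
#' paired with a representative density chosen by `pairing` (arithmetic
#' midpoint by default). Replicates are averaged *before* the log-difference
#' is taken, so each seeding condition contributes one profile.
#'
#' @param data A data frame with columns `time_h` and `density`, and
#'   optionally `replicate` and `seeding`. Multiple seedings are processed
#'   independently.
#' @param pairing Which density accompanies each rate increment:
#'   `"midpoint"` (\eqn{(\bar x_i + \bar x_{i+1})/2}), `"left"`
#'   (\eqn{\bar x_i}), or `"geometric_mean"`
#'   (\eqn{\sqrt{\bar x_i \bar x_{i+1}}}).
#' @return A tibble with columns `seeding` (if present in the input),
#'   `interval` (index of the consecutive pair), `density`, and `rpr`.
#'   A series of `m` time points yields `m - 1` profile points.
#'
#' @examples
#' ts <- tibble::tibble(time_h = seq(0, 10, 2),
#'                      density = 0.2 * exp(0.05 * seq(0, 10, 2)))
#' rpr_profile(ts) # all rpr values equal 0.05
#' @export
rpr_profile <- function(data, pairing = c("midpoint", "left",
                                          "geometric_mean")) {
  pairing <- match.arg(pairing)
  if (!all(c("time_h", "density") %in% names(data)))
    abort("rpr_profile: `data` needs columns `time_h` and `density`")
  has_seeding <- "seeding" %in% names(data)
  if (!has_seeding) data$seeding <- "1"
  mean_series <- data |>
    dplyr::group_by(.data$seeding, .data$time_h) |>
    dplyr::summarise(density = mean(.data$density), .groups = "drop") |>
    dplyr::arrange(.data$seeding, .data$time_h)
  bad <- mean_series |> dplyr::filter(.data$density <= 0)
  if (nrow(bad))
    abort(sprintf(
      "rpr_profile: non-positive mean density at time %s (seeding %s); Fisher RGR needs positive densities",
      format(bad$time_h[1]), bad$seeding[1]))
  out <- mean_series |>
    dplyr::group_by(.data$seeding) |>
    dplyr::reframe({
      x <- .data$density; t <- .data$time_h
      m <- length(x)
      if (m < 2L) abort("rpr_profile: need at least two time points")
      i <- seq_len(m - 1L)
      dens <- switch(pairing,
                     midpoint = (x[i] + x[i + 1L]) / 2,
                     left = x[i],
                     geometric_mean = sqrt(x[i] * x[i + 1L]))
      tibble(interval = i,
             density = dens,
             rpr = (log(x[i + 1L]) - log(x[i])) / (t[i + 1L] - t[i]))
    })
  if (!has_seeding) out$seeding <- NULL
  out
}

#' Residual sum of squares of a hexad against an RPR profile
#'
#' \eqn{\sum_i (RPR_i - f(x_i)/x_i)^2} with the model RPR evaluated at the
#' profile densities — the objective minimised by [grid_search()].
#'
#' @inheritParams apr
#' @param profile A profile from [rpr_profile()] (one seeding).
#' @return Nonnegative scalar.
#' @export
rss_rpr <- function(params, profile) {
  assert_growth_params(params)
  if (!all(c("density", "rpr") %in% names(profile)) || nrow(profile) == 0)
    abort("rss_rpr: `profile` must be a non-empty rpr_profile() result")
  if ("seeding" %in% names(profile) && length(unique(profile$seeding)) > 1)
    abort("rss_rpr: `profile` mixes seedings; fit one at a time")
  sum((profile$rpr - rpr(params, profile$density))^2)
}

#' Residual sum of squares of a hexad against a density time series
#'
#' Integrates the growth law from `x0` at the observed times and returns
#' \eqn{\sum_i (\bar x_i - \hat x_i)^2} on the replicate-mean series.
#'
#' @inheritParams apr
#' @param data Data frame as in [rpr_profile()] (a single seeding).
#' @param x0 Initial model density; defaults to the first observed mean
#'   density.
#' @return Nonnegative scalar.
#' @export
rss_density <- function(params, data, x0 = NULL) {
  assert_growth_params(params)
  if ("seeding" %in% names(data) && length(unique(data$seeding)) > 1)
    abort("rss_density: `data` mixes seedings; fit one at a time")
  ms <- data |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(density = mean(.data$density), .groups = "drop") |>
    dplyr::arrange(.data$time_h)
  x0 <- x0 %||% ms$density[1]
  if (x0 <= 0) abort("rss_density: `x0` must be > 0")
  tr <- solve_trajectory(params, x0, ms$time_h)
  sum((ms$density - tr$density)^2)
}
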