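#' Rate profiles of a parameter hexad
#'
#' Plots the absolute and relative proliferation rate against density, with
#' equilibria marked — the standard visual summary of the growth law's
#' bistable structure.
#'
#' @inheritParams apr
#' @param upper Upper density limit of the plot (default `1.1 * K`).
#' @param n Number of evaluation points.
#' @return A ggplot object (two facets: APR and RPR).
#' @export
plot_rate_profiles <- function(params, upper = 1.1 * params$K, n = 400L) {
  assert_growth_params(params)
  x <- seq(upper / n, upper, length.out = n)
  df <- dplyr::bind_rows(
    tibble(density = x, rate = apr(params, x), profile = "APR (dx/dt)"),
    tibble(density = x, rate = rpr(params, x), profile = "RPR (dx/dt per cell)"))
  eq <- find_equilibria(params)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$density, y = .data$rate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = eq$density[eq$density > 0],
                        linetype = 3, colour = "firebrick") +
    ggplot2::facet_wrap(~profile, scales = "free_y") +
    ggplot2::labs(x = "scaled cell density", y = "rate (per h)")
}

#' @describeIn stationary_pdf Plot a stationary density.
#' @param object,... `autoplot` method arguments.
#' @export
autoplot.sspdf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$density, y = .data$pdf)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "scaled cell density", y = "stationary density",
                  title = "Stationary cell-density distribution")
}

#' @describeIn simulate_ensemble Histogram of the terminal densities with
#'   the matching analytic stationary density overlaid when available.
#' @param object,... `autoplot` method arguments.
#' @export
autoplot.growth_ensemble <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$final_density)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 40, fill = "grey75", colour = "grey40") +
    ggplot2::labs(x = "terminal scaled cell density", y = "density",
                  title = sprintf("Terminal densities (%d paths, T = %g h)",
                                  object$n_paths, object$horizon))
  if (object$noise$D + object$noise$Q > 0) {
    ss <- stationary_pdf(object$params, object$noise)
    p <- p + ggplot2::geom_line(
      data = ss, ggplot2::aes(x = .data$density, y = .data$pdf),
      colour = "steelblue", linewidth = 0.8)
  }
  p
}
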