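# Shared fixtures: the three fitted scratch-assay hexads and a small helper
# for drawing random valid hexads in property-style tests.

p1 <- assay_params(1)
p2 <- assay_params(2)
p3 <- assay_params(3)

random_hexad <- function(alpha_eq_delta = FALSE) {
  r_p <- runif(1, 0.1, 0.5)
  n <- runif(1, 0, 0.8 * r_p)
  a <- runif(1, 0.3, 2)
  growth_params(r_p = r_p, K = runif(1, 1, 3), n = n,
                alpha = a, beta = runif(1, 0.5, 2),
                delta = if (alpha_eq_delta) a else runif(1, 0.1, 2))
}

# Direct double-loop RSS oracle for small grids, independent of the
# factorised search engine.
brute_force_search <- function(profile, grid) {
  combos <- expand.grid(id = seq_along(grid$delta), ib = seq_along(grid$beta),
                        ia = seq_along(grid$alpha), `in` = seq_along(grid$n),
                        ik = seq_along(grid$K), ir = seq_along(grid$r_p))
  best <- Inf; best_p <- NULL
  for (row in seq_len(nrow(combos))) {
    cb <- combos[row, ]
    p <- growth_params(grid$r_p[cb$ir], grid$K[cb$ik], grid$n[cb$`in`],
                       grid$alpha[cb$ia], grid$beta[cb$ib], grid$delta[cb$id])
    r <- sum((profile$rpr - rpr(p, profile$density))^2)
    if (r < best) { best <- r; best_p <- p }
  }
  list(params = best_p, rss = best)
}

ks_distance_to_sspdf <- function(ensemble, sspdf) {
  cdf <- as.numeric(pracma::cumtrapz(sspdf$density, sspdf$pdf))
  cdf <- cdf / cdf[length(cdf)]
  emp <- stats::ecdf(ensemble$final_densities)
  max(abs(emp(sspdf$density) - cdf))
}
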