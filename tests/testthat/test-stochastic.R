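test_that("noise-induced drift reduces correctly in its limit cases", {
  x <- seq(0.1, 2, length.out = 20)
  off <- noise_params(0, 0, 0)
  expect_equal(drift_A(p1, off, x), apr(p1, x), tolerance = 1e-15)
  # lambda = 0 removes the cross term only
  no <- noise_params(D = 0.02, Q = 0.05, lambda = 0)
  expect_equal(drift_A(p1, no, x) - apr(p1, x),
               0.02 * (p1$delta + 1) * x^(2 * p1$delta + 1),
               tolerance = 1e-14)
  # frozen term-by-term evaluation at x = 1, D = Q = 0.01, lambda = 0.5
  expect_equal(drift_A(p1, noise_params(0.01, 0.01, 0.5), 1),
               0.035265168306707093, tolerance = 1e-12)
})

test_that("diffusion is the stated quadratic form and stays nonnegative", {
  expect_identical(diffusion_B(p1, noise_params(0.03, 0.07, -0.2), 0), 0.07)
  # hand arithmetic: D x^(2.4) - 2*0.5*0.01*x^(1.2) + Q at x = 1
  expect_equal(diffusion_B(p1, noise_params(0.01, 0.01, 0.5), 1), 0.01,
               tolerance = 1e-15)
  # lambda = 1 is a perfect square vanishing at (Q/D)^(1/(2 delta + 2))
  no1 <- noise_params(0.01, 0.01, 1)
  xz <- (no1$Q / no1$D)^(1 / (2 * p1$delta + 2))
  expect_equal(diffusion_B(p1, no1, xz), 0, tolerance = 1e-15)
  x <- seq(0, 3, length.out = 50)
  expect_equal(diffusion_B(p1, no1, x),
               (sqrt(no1$D) * x^(p1$delta + 1) - sqrt(no1$Q))^2,
               tolerance = 1e-14)
  # property: B >= (1 - |lambda|)(D x^(2d+2) + Q) >= 0 under random draws
  set.seed(41)
  for (i in 1:25) {
    p <- random_hexad()
    no <- noise_params(runif(1, 0, 0.1), runif(1, 0, 0.1), runif(1, -1, 1))
    x <- runif(10, 0, 3 * p$K)
    B <- diffusion_B(p, no, x)
    lb <- (1 - abs(no$lambda)) * (no$D * x^(2 * p$delta + 2) + no$Q)
    expect_true(all(B >= lb - 1e-12))
  }
})

test_that("stationary density is normalised with vanishing flux", {
  for (no in list(noise_params(0.002, 0.06, 0.4),
                  noise_params(0.01, 0.01, 0.5))) {
    ss <- stationary_pdf(p1, no)
    expect_lte(attr(ss, "normalization_residual"), 1e-6)
    expect_equal(pracma::trapz(ss$density, ss$pdf), 1, tolerance = 1e-6)
    fl <- stationary_flux(ss)
    scale <- max(abs(drift_A(p1, no, ss$density) * ss$pdf))
    expect_lte(max(abs(fl$flux)) / scale, 1e-4)
  }
  expect_error(stationary_pdf(p1, noise_params(0, 0, 0)), "D \\+ Q")
})

test_that("small noise concentrates the density at the MSSCD", {
  ss <- stationary_pdf(p1, noise_params(1e-5, 1e-5, 0))
  mode <- ss$density[which.max(ss$pdf)]
  expect_equal(mode, 1.3507, tolerance = 0.01)
})

test_that("perfectly correlated noise with interior diffusion zero is flagged", {
  ss <- stationary_pdf(p1, noise_params(0.01, 0.01, 1))
  expect_true(attr(ss, "regularized"))
  expect_lte(attr(ss, "normalization_residual"), 1e-6)
})

test_that("density extrema solve A - B' = 0 and have deterministic limits", {
  # vanishing-noise continuation: the two upper roots approach the interior
  # equilibria (the cross-noise term also seeds a root at x ~ 0)
  ex <- sspdf_extrema(p1, noise_params(1e-7, 1e-7, 0.3))
  expect_equal(tail(ex, 2), c(0.0671, 1.3507), tolerance = 5e-3)
  # D = 0, lambda = 0: A - B' = f exactly, so extrema are the equilibria
  ex0 <- sspdf_extrema(p1, noise_params(0, 0.02, 0))
  eq <- find_equilibria(p1)
  expect_equal(ex0, eq$density[eq$density > 0], tolerance = 1e-9)
  # cross-module: extrema coincide with grid extrema of the computed density
  no <- noise_params(0.01, 0.01, 0.5)
  ss <- stationary_pdf(p1, no)
  ex <- sspdf_extrema(p1, no)
  h <- diff(ss$density[1:2])
  P <- ss$pdf
  interior <- which(diff(sign(diff(P))) != 0) + 1L
  grid_ex <- ss$density[interior]
  for (e in ex[ex > 10 * h])
    expect_lte(min(abs(grid_ex - e)), 2 * h)
})

test_that("stochastic MSSCD approximation behaves as the theory states", {
  # noiseless limit: frozen first-order value, within 1% of the numeric root
  res <- mssd_stochastic_approx(p1, noise_params(0, 0, 0))
  expect_equal(res$value, 1.3593106645204292, tolerance = 1e-12)
  expect_equal(res$value, 1.3507, tolerance = 0.01)
  expect_true(res$condition_met)
  # lambda = 0 must equal an independent evaluation without cross terms
  no <- noise_params(0.02, 0.05, 0)
  K <- p1$K; d <- p1$delta
  num <- p1$n * K^(d + 1) + 0.02 * (d + 1) * K^(2 * d + 1)
  den <- p1$beta * p1$r_p * K^(p1$alpha + 1) + p1$n * (d + 1) * K^(d + 1) +
    0.02 * (d + 1) * (2 * d + 1) * K^(2 * d + 1)
  expect_equal(mssd_stochastic_approx(p1, no)$value, K - K * num / den,
               tolerance = 1e-14)
  # increases with Q at fixed D, decreases with D at fixed Q (lambda = 1)
  qs <- seq(0, 0.1, by = 0.02)
  vq <- vapply(qs, function(q)
    mssd_stochastic_approx(p1, noise_params(0.01, q, 1))$value, numeric(1))
  expect_true(all(diff(vq) > 0))
  ds <- seq(0, 0.1, by = 0.02)
  vd <- vapply(ds, function(dd)
    mssd_stochastic_approx(p1, noise_params(dd, 0.01, 1))$value, numeric(1))
  expect_true(all(diff(vd) < 0))
  # continuity: (D, Q) -> 0 approaches the noiseless value
  small <- mssd_stochastic_approx(p1, noise_params(1e-9, 1e-9, 0.7))$value
  expect_equal(small, res$value, tolerance = 1e-6)
})

test_that("ensembles are reproducible and recover the noiseless ODE", {
  no <- noise_params(0.01, 0.02, 0.3)
  e1 <- simulate_ensemble(p1, no, 0.5, horizon = 5, dt = 0.01, n_paths = 40,
                          seed = 99)
  e2 <- simulate_ensemble(p1, no, 0.5, horizon = 5, dt = 0.01, n_paths = 40,
                          seed = 99)
  expect_identical(e1$final_densities, e2$final_densities)
  e3 <- simulate_ensemble(p1, no, 0.5, horizon = 5, dt = 0.01, n_paths = 40,
                          seed = 100)
  expect_false(identical(e1$final_densities, e3$final_densities))
  # zero noise: every path is the deterministic trajectory
  det <- simulate_ensemble(p1, noise_params(0, 0, 0), 0.5, horizon = 40,
                           dt = 1e-3, n_paths = 3, seed = 1)
  ode <- solve_trajectory(p1, 0.5, c(0, 40))
  expect_equal(det$final_densities, rep(tail(ode$density, 1), 3),
               tolerance = 1e-4)
})

test_that("the two integration schemes agree in distribution", {
  no <- noise_params(0.002, 0.06, 0.4)
  a <- simulate_ensemble(p1, no, 0.5, horizon = 150, dt = 0.01,
                         n_paths = 2000, seed = 51, scheme = "ito_em")
  b <- simulate_ensemble(p1, no, 0.5, horizon = 150, dt = 0.01,
                         n_paths = 2000, seed = 52,
                         scheme = "stratonovich_heun")
  grid <- seq(0, 3 * p1$K, length.out = 400)
  ks <- max(abs(stats::ecdf(a$final_densities)(grid) -
                  stats::ecdf(b$final_densities)(grid)))
  expect_lte(ks, 0.06)
})

test_that("mode classification validates inputs", {
  en <- simulate_ensemble(p1, noise_params(0.01, 0.01, 0.5), 1, horizon = 1,
                          dt = 0.01, n_paths = 50, seed = 5)
  expect_error(classify_steady_state(en), "100")
})
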