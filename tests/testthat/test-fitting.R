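test_that("Fisher RGR of an exponential is its rate, everywhere", {
  t <- c(seq(0, 18, 2), seq(24, 48, 6))
  ts <- tibble::tibble(time_h = t, density = 0.2 * exp(0.05 * t))
  prof <- rpr_profile(ts)
  expect_equal(nrow(prof), length(t) - 1L)
  expect_equal(prof$rpr, rep(0.05, nrow(prof)), tolerance = 1e-12)
  # two-point hand oracle: RPR = ln(1.2)/2 at midpoint density 1.1
  two <- rpr_profile(tibble::tibble(time_h = c(0, 2), density = c(1, 1.2)))
  expect_equal(two$rpr, 0.09116077839697731, tolerance = 1e-12)
  expect_equal(two$density, 1.1)
  # pairing policies
  expect_equal(rpr_profile(tibble::tibble(time_h = c(0, 2),
                                          density = c(1, 1.2)),
                           pairing = "left")$density, 1)
  expect_equal(rpr_profile(tibble::tibble(time_h = c(0, 2),
                                          density = c(1, 1.2)),
                           pairing = "geometric_mean")$density, sqrt(1.2))
  # constant series has identically zero profile
  const <- rpr_profile(tibble::tibble(time_h = t, density = rep(0.7, 15)))
  expect_true(all(const$rpr == 0))
  expect_error(rpr_profile(tibble::tibble(time_h = c(0, 2),
                                          density = c(1, 0))),
               "non-positive")
})

test_that("replicates are averaged before the log-difference", {
  t <- seq(0, 10, 2)
  base <- 0.3 * exp(0.04 * t)
  reps <- dplyr::bind_rows(
    tibble::tibble(time_h = t, density = base + 0.05, replicate = 1),
    tibble::tibble(time_h = t, density = base - 0.05, replicate = 2))
  means <- tibble::tibble(time_h = t, density = base)
  expect_equal(rpr_profile(reps)$rpr, rpr_profile(means)$rpr,
               tolerance = 1e-12)
})

test_that("RPR residual sum of squares matches hand computation", {
  prof <- tibble::tibble(density = c(0.3, 0.8, 1.2),
                         rpr = c(0.02, 0.015, 0.004))
  manual <- sum((prof$rpr - rpr(p1, prof$density))^2)
  expect_equal(rss_rpr(p1, prof), manual, tolerance = 1e-15)
  # exact-model profile scores zero, and an eps perturbation scores eps^2
  exact <- tibble::tibble(density = c(0.3, 0.8, 1.2),
                          rpr = rpr(p1, c(0.3, 0.8, 1.2)))
  expect_identical(rss_rpr(p1, exact), 0)
  exact$rpr[2] <- exact$rpr[2] + 1e-3
  expect_equal(rss_rpr(p1, exact), 1e-6, tolerance = 1e-12)
})

test_that("density RSS is zero on model data and ~ m sigma^2 under noise", {
  t <- c(seq(0, 18, 2), seq(24, 48, 6))
  tr <- solve_trajectory(p1, 0.1, t)
  ts <- tibble::tibble(time_h = t, density = tr$density)
  expect_lt(rss_density(p1, ts), 1e-10)
  # Monte-Carlo: additive N(0, sigma) observation noise inflates the RSS to
  # m sigma^2 in expectation
  sigma <- 0.02
  set.seed(31)
  rss <- replicate(1000, {
    noisy <- ts
    noisy$density <- pmax(noisy$density + rnorm(15, 0, sigma), 1e-6)
    sum((noisy$density - tr$density)^2)
  })
  expect_equal(mean(rss), 15 * sigma^2, tolerance = 0.05)
})

test_that("grid search equals the brute-force oracle on a toy grid", {
  g <- param_grid(r_p = c(0.1, 0.2), K = c(1.2, 1.8), n = c(0.005, 0.02),
                  alpha = c(0.5, 1.2), beta = c(0.8, 1.5),
                  delta = c(0.2, 0.9))
  truth <- growth_params(0.2, 1.8, 0.005, 1.2, 0.8, 0.9)
  dens <- seq(0.15, 1.6, length.out = 12)
  prof <- tibble::tibble(density = dens, rpr = rpr(truth, dens))
  fit <- grid_search(prof, g)
  oracle <- brute_force_search(prof, g)
  expect_equal(unclass(fit$params), unclass(oracle$params))
  expect_equal(fit$rss_rpr, oracle$rss, tolerance = 1e-12)
  expect_equal(fit$n_evaluated, 64)
  # determinism: same inputs, identical output
  expect_identical(tidy(fit), tidy(grid_search(prof, g)))
})

test_that("a 4^6 search recovers an on-grid hexad and matches the oracle", {
  g <- param_grid(r_p = c(0.03, 0.13, 0.23, 0.33),
                  K = c(1.03, 1.43, 1.83, 2.23),
                  n = c(0.0035, 0.0095, 0.0155, 0.0215),
                  alpha = c(0.9, 1.15, 1.4, 1.65),
                  beta = c(0.59, 0.99, 1.39, 1.79),
                  delta = c(0.2, 1.0, 1.8, 2.6))
  dens <- seq(0.1, 1.3, length.out = 14)
  prof <- tibble::tibble(density = dens, rpr = rpr(p1, dens))
  t0 <- Sys.time()
  fit <- grid_search(prof, g)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 5)
  expect_equal(unclass(fit$params), unclass(p1))
  expect_lt(fit$rss_rpr, 1e-20)
  expect_equal(fit$n_evaluated, 4^6)
  # noisy profile: the arg-min can only improve on the generating hexad
  set.seed(32)
  noisy <- prof
  noisy$rpr <- noisy$rpr + rnorm(14, 0, 0.005)
  nfit <- grid_search(noisy, g)
  expect_lte(nfit$rss_rpr, rss_rpr(p1, noisy))
})

test_that("logistic baseline: recovery, hand oracle, nesting inequality", {
  r_grid <- c(0.02, 0.04, 0.06, 0.08)
  K_grid <- c(1.5, 2.0, 2.5, 3.0)
  truth <- growth_params(r_p = 0.06, K = 2.5, n = 0, alpha = 0, beta = 1)
  dens <- seq(0.2, 2.2, length.out = 10)
  prof <- tibble::tibble(density = dens, rpr = rpr(truth, dens))
  fit <- fit_logistic(prof, r_grid, K_grid)
  expect_equal(fit$params$r_p, 0.06)
  expect_equal(fit$params$K, 2.5)
  expect_lt(fit$rss_rpr, 1e-25)
  expect_equal(fit$model, "logistic")
  # hand least-squares oracle on 3 points for a fixed (r, K)
  small <- tibble::tibble(density = c(0.5, 1.0, 1.5),
                          rpr = c(0.04, 0.03, 0.01))
  pl <- growth_params(0.05, 2, n = 0, alpha = 0, beta = 1)
  manual <- sum((small$rpr - 0.05 * (1 - small$density / 2))^2)
  expect_equal(rss_rpr(pl, small), manual, tolerance = 1e-15)
  # nested grids: the full model can never do worse than the logistic
  gfull <- param_grid(r_p = r_grid, K = K_grid, n = c(0, 0.01),
                      alpha = c(0, 1), beta = c(1, 2), delta = c(0, 1))
  set.seed(33)
  noisy <- prof
  noisy$rpr <- noisy$rpr + rnorm(10, 0, 0.004)
  expect_lte(grid_search(noisy, gfull)$rss_rpr,
             fit_logistic(noisy, r_grid, K_grid)$rss_rpr)
})
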