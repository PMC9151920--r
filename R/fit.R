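#' Parameter grid for exhaustive hexad search
#'
#' One ascending list of candidate values per parameter; [grid_search()]
#' evaluates the full Cartesian product. [assay_presets()] ships grids
#' mirroring the published scratch-assay protocol (10 values per parameter,
#' hence 10^6 hexads per seeding).
#'
#' @param r_p,K,n,alpha,beta,delta Ascending numeric vectors of candidate
#'   values (each non-empty and finite; the usual hexad constraints apply to
#'   the admissible combinations, not to every listed value).
#' @return An object of class `param_grid`.
#' @export
param_grid <- function(r_p, K, n, alpha, beta, delta) {
  g <- list(r_p = r_p, K = K, n = n, alpha = alpha, beta = beta,
            delta = delta)
  for (nm in names(g)) {
    v <- g[[nm]]
    if (!is.numeric(v) || length(v) == 0L || any(!is.finite(v)))
      abort(sprintf("param_grid: `%s` must be a non-empty finite numeric vector", nm))
    if (is.unsorted(v, strictly = TRUE))
      abort(sprintf("param_grid: `%s` must be strictly ascending", nm))
    g[[nm]] <- as.numeric(v)
  }
  structure(g, class = "param_grid")
}

#' @export
print.param_grid <- function(x, ...) {
  cat("<param_grid>", format(prod(lengths(unclass(x))), big.mark = ","),
      "hexads\n")
  for (nm in names(unclass(x)))
    cat(sprintf("  %-5s (%d): %s\n", nm, length(x[[nm]]),
                paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}

new_growth_fit <- function(params, rss_rpr, n_evaluated, model,
                           rss_density = NA_real_) {
  structure(list(params = params, rss_rpr = rss_rpr,
                 rss_density = rss_density, n_evaluated = n_evaluated,
                 model = model),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> %s model, %s hexads evaluated\n", x$model,
              format(x$n_evaluated, big.mark = ",")))
  print(x$params)
  cat(sprintf("  RSS (RPR profile): %.6g\n", x$rss_rpr))
  if (!is.na(x$rss_density))
    cat(sprintf("  RSS (density profile): %.6g\n", x$rss_density))
  invisible(x)
}

#' @export
tidy.growth_fit <- function(x, ...) tidy(x$params)

#' @export
glance.growth_fit <- function(x, ...) {
  tibble(model = x$model, rss_rpr = x$rss_rpr, rss_density = x$rss_density,
         n_evaluated = x$n_evaluated)
}

# Factorised RSS evaluation over the full Cartesian product.
#
# For fixed (K, beta, alpha) the model RPR is linear in (r_p, n):
#   m_j = r_p * u_j - n * v_j,  u = x^alpha (1 - (x/K)^beta),  v = x^delta,
# so the RSS over all (r_p, n, delta) combinations expands into dot
# products of u, v and the observations — no per-hexad loop. Streaming
# arg-min keeps memory O(levels), not O(product).
grid_search_engine <- function(x, y, grid, progress = FALSE) {
  Rv <- grid$r_p; Kv <- grid$K; Nv <- grid$n
  Av <- grid$alpha; Bv <- grid$beta; Dv <- grid$delta
  V <- vapply(Dv, function(d) x^d, numeric(length(x)))   # m x nD
  vv <- colSums(V * V)
  yv <- as.numeric(crossprod(y, V))
  yy <- sum(y * y)
  RN <- outer(Rv, Nv)
  nR <- length(Rv); nN <- length(Nv)
  best <- Inf
  best_idx <- NULL
  it <- 0L; total <- length(Kv) * length(Bv) * length(Av)
  for (ik in seq_along(Kv)) for (ib in seq_along(Bv)) {
    xkb <- (x / Kv[ik])^Bv[ib]
    for (ia in seq_along(Av)) {
      u <- x^Av[ia] * (1 - xkb)
      yu <- sum(y * u); uu <- sum(u * u)
      uv <- as.numeric(crossprod(u, V))
      base_r <- yy - 2 * Rv * yu + Rv^2 * uu        # length nR
      for (id in seq_along(Dv)) {
        M <- base_r +
          rep(2 * Nv * yv[id] + Nv^2 * vv[id], each = nR) -
          2 * uv[id] * RN
        mn <- min(M)
        if (mn <= best) {
          pos <- which(M == mn, arr.ind = TRUE)
          if (is.null(dim(pos))) pos <- matrix(pos, ncol = 2)
          pos <- pos[order(pos[, 1], pos[, 2]), , drop = FALSE]
          for (pr in seq_len(nrow(pos))) {
            cand <- c(pos[pr, 1], ik, pos[pr, 2], ia, ib, id)
            if (mn < best ||
                (mn == best && lex_less(cand, best_idx))) {
              best <- mn; best_idx <- cand
            }
          }
        }
      }
      it <- it + 1L
      if (progress && it %% max(1L, total %/% 20L) == 0L)
        message(sprintf("grid_search: %d / %d parameter blocks", it, total))
    }
  }
  list(idx = best_idx, rss = best)
}

lex_less <- function(a, b) {
  d <- a - b
  i <- which(d != 0)
  length(i) > 0 && d[i[1]] < 0
}

#' Exhaustive grid search for the best-fitting hexad
#'
#' Evaluates the RPR-profile residual sum of squares on the *full* Cartesian
#' product of the candidate lists and returns the arg-min hexad. Ties are
#' broken by lexicographically smallest grid indices in the order
#' `(r_p, K, n, alpha, beta, delta)`. With the published-protocol grids
#' (10 values per parameter) this examines 10^6 hexads; the evaluation is
#' factorised over the grid levels so the search takes seconds, with O(1)
#' memory per hexad.
#'
#' @param profile An RPR profile from [rpr_profile()] (one seeding).
#' @param grid A [param_grid()].
#' @param data Optional density time series; when supplied, the density-RSS
#'   of the winning hexad is computed via [rss_density()].
#' @param x0 Optional initial density for the density-RSS (defaults to the
#'   first observed mean density).
#' @param progress Emit progress messages.
#' @return A `growth_fit` object; see [tidy()] and [glance()] methods.
#'
#' @examples
#' p <- growth_params(0.13, 1.43, 0.0095, 1.15, 0.99, 0.2)
#' prof <- tibble::tibble(density = seq(0.2, 1.2, length.out = 10),
#'                        rpr = rpr(p, seq(0.2, 1.2, length.out = 10)))
#' g <- param_grid(r_p = c(0.03, 0.13), K = c(1.43, 2), n = c(0.0095, 0.02),
#'                 alpha = c(0.5, 1.15), beta = c(0.99, 2), delta = c(0.2, 1))
#' grid_search(prof, g)
#' @export
grid_search <- function(profile, grid, data = NULL, x0 = NULL,
                        progress = FALSE) {
  if (!inherits(grid, "param_grid"))
    abort("grid_search: `grid` must be a param_grid object")
  if (!all(c("density", "rpr") %in% names(profile)) || nrow(profile) == 0)
    abort("grid_search: `profile` must be a non-empty rpr_profile() result")
  res <- grid_search_engine(profile$density, profile$rpr, grid, progress)
  idx <- res$idx
  best <- growth_params(r_p = grid$r_p[idx[1]], K = grid$K[idx[2]],
                        n = grid$n[idx[3]], alpha = grid$alpha[idx[4]],
                        beta = grid$beta[idx[5]], delta = grid$delta[idx[6]])
  fit <- new_growth_fit(best, rss_rpr = rss_rpr(best, profile),
                        n_evaluated = prod(lengths(unclass(grid))),
                        model = "extended_logistic")
  if (!is.null(data)) fit$rss_density <- rss_density(best, data, x0 = x0)
  fit
}

#' Logistic baseline fit of an RPR profile
#'
#' Same grid-search machinery restricted to the plain logistic special case
#' (`alpha = 0`, `beta = 1`, `n = 0`), whose RPR is the line
#' \eqn{r(1 - x/K)}. Serves as the nested baseline for model comparison: over
#' nested grids the full model's minimised RSS can never exceed the
#' logistic's.
#'
#' @inheritParams grid_search
#' @param r_grid,K_grid Ascending candidate vectors for `r` and `K`.
#' @return A `growth_fit` with `model = "logistic"`.
#' @export
fit_logistic <- function(profile, r_grid, K_grid, data = NULL, x0 = NULL) {
  g <- param_grid(r_p = r_grid, K = K_grid, n = 0, alpha = 0, beta = 1,
                  delta = 0)
  fit <- grid_search(profile, g, data = data, x0 = x0)
  fit$model <- "logistic"
  fit$n_evaluated <- length(r_grid) * length(K_grid)
  fit
}
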