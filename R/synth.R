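#' Scratch-assay design for synthetic data generation
#'
#' Describes the wound-healing (scratch) assay layout the synthetic
#' generator emulates: several initial seeding conditions, a few replicates
#' per condition, and an observation grid that samples every 2 h for the
#' first 18 h and then every 6 h up to 48 h (15 time points).
#'
#' @param n_seedings Number of seeding conditions.
#' @param n_replicates Replicates per seeding condition.
#' @param times Observation grid in hours.
#' @param initial_densities One initial scaled density per seeding (the
#'   defaults loosely mirror 12k/16k/20k cells-per-well seeding ratios).
#' @param obs_noise_sd Standard deviation of additive Gaussian observation
#'   noise on densities (truncated at 0); roughly 1–2% of a typical carrying
#'   capacity by default. The true assay error magnitude is unknown; this is
#'   a placeholder to be tuned per application.
#' @param seed Integer seed for the observation noise.
#' @return An object of class `assay_design`.
#' @export
assay_design <- function(n_seedings = 3L, n_replicates = 3L,
                         times = c(seq(0, 18, by = 2), seq(24, 48, by = 6)),
                         initial_densities = c(0.1, 0.15, 0.2),
                         obs_noise_sd = 0.02, seed = 1L) {
  if (any(diff(times) <= 0))
    abort("assay_design: `times` must be strictly increasing")
  if (length(initial_densities) != n_seedings)
    abort("assay_design: need one initial density per seeding")
  if (any(initial_densities <= 0))
    abort("assay_design: initial densities must be > 0")
  if (obs_noise_sd < 0) abort("assay_design: `obs_noise_sd` must be >= 0")
  structure(list(n_seedings = as.integer(n_seedings),
                 n_replicates = as.integer(n_replicates),
                 times = as.numeric(times),
                 initial_densities = as.numeric(initial_densities),
                 obs_noise_sd = obs_noise_sd, seed = as.integer(seed)),
            class = "assay_design")
}

#' Generate a synthetic scratch-assay time series
#'
#' Integrates the deterministic growth law from each seeding's initial
#' density over the design's observation grid and adds independent Gaussian
#' observation noise (sd `obs_noise_sd`, truncated at 0) per replicate and
#' time point. Noise touches densities only, never times. Deterministic
#' given `design$seed`.
#'
#' @param params A single [growth_params()] hexad used for every seeding, or
#'   a list of one hexad per seeding.
#' @param design An [assay_design()].
#' @return A tibble with columns `time_h`, `density`, `replicate`,
#'   `seeding` — the CSV dialect accepted by [rpr_profile()] and
#'   [write_timeseries()].
#'
#' @examples
#' p <- growth_params(0.13, 1.43, 0.0095, 1.15, 0.99, 0.2)
#' d <- assay_design(n_seedings = 1, initial_densities = 0.1,
#'                   obs_noise_sd = 0, seed = 7)
#' synth_timeseries(p, d)
#' @export
synth_timeseries <- function(params, design) {
  if (!inherits(design, "assay_design"))
    abort("synth_timeseries: `design` must come from assay_design()")
  plist <- if (inherits(params, "growth_params"))
    rep(list(params), design$n_seedings)
  else params
  if (length(plist) != design$n_seedings)
    abort("synth_timeseries: need one hexad, or one per seeding")
  lapply(plist, assert_growth_params)
  set.seed(design$seed)
  purrr::map_dfr(seq_len(design$n_seedings), function(s) {
    tr <- solve_trajectory(plist[[s]], design$initial_densities[s],
                           design$times)
    purrr::map_dfr(seq_len(design$n_replicates), function(r) {
      noise <- if (design$obs_noise_sd > 0)
        rnorm(length(design$times), 0, design$obs_noise_sd) else 0
      tibble(time_h = design$times,
             density = pmax(tr$density + noise, 0),
             replicate = r, seeding = s)
    })
  })
}

#' Read / write the scratch-assay CSV dialect
#'
#' The on-disk format is a UTF-8 CSV with header
#' `time_h,density,replicate,seeding` and decimal-float densities. The
#' reader validates that densities are nonnegative, that each replicate's
#' time grid is strictly increasing, and that all replicates within a
#' seeding share the same grid; violations are reported with the offending
#' row or series.
#'
#' @param path File path.
#' @param data A tibble in the dialect (e.g. from [synth_timeseries()]).
#' @return `read_timeseries()` returns the validated tibble;
#'   `write_timeseries()` returns `data` invisibly. Round-tripping is the
#'   identity on valid data.
#' @export
read_timeseries <- function(path) {
  data <- readr::read_csv(path, col_types = readr::cols(
    time_h = readr::col_double(), density = readr::col_double(),
    replicate = readr::col_character(), seeding = readr::col_character()))
  validate_timeseries(data)
  data
}

#' @rdname read_timeseries
#' @export
write_timeseries <- function(data, path) {
  validate_timeseries(data)
  readr::write_csv(data, path)
  invisible(data)
}

validate_timeseries <- function(data) {
  need <- c("time_h", "density", "replicate", "seeding")
  miss <- setdiff(need, names(data))
  if (length(miss))
    abort(paste0("timeseries: missing columns: ", paste(miss, collapse = ", ")))
  bad <- which(!is.finite(data$density) | data$density < 0)
  if (length(bad))
    abort(sprintf("timeseries: negative or non-finite density at row %d", bad[1]))
  grids <- data |>
    dplyr::group_by(.data$seeding, .data$replicate) |>
    dplyr::summarise(mono = all(diff(.data$time_h) > 0),
                     grid = paste(.data$time_h, collapse = ","),
                     .groups = "drop")
  nm <- grids |> dplyr::filter(!.data$mono)
  if (nrow(nm))
    abort(sprintf(
      "timeseries: non-monotone time grid in seeding %s, replicate %s",
      nm$seeding[1], nm$replicate[1]))
  mis <- grids |>
    dplyr::group_by(.data$seeding) |>
    dplyr::summarise(aligned = dplyr::n_distinct(.data$grid) == 1L,
                     .groups = "drop") |>
    dplyr::filter(!.data$aligned)
  if (nrow(mis))
    abort(sprintf(
      "timeseries: replicates of seeding %s are on mismatched time grids",
      mis$seeding[1]))
  invisible(data)
}
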