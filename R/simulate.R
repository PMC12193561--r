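#' Configuration for the synthetic registry-data generator
#'
#' Describes a synthetic SEER-like case listing: for each diagnosis year in
#' `range`, `n_per_year` patients draw an individual survival time whose
#' distribution has mean equal to the ground-truth trend curve at that year.
#' Defaults emulate the kidney & renal pelvis cancer setting the method was
#' developed on: calendar years 1992--2020, a 20-year window, a slowly
#' doubling exponential improvement trend, right-skewed individual survival
#' times, and integer-year rounding as in registry extracts.
#'
#' The truth curve is the mean of the *untruncated* survival distribution;
#' configurations must keep it strictly inside `(0, window_N)` so that the
#' window truncation applied when building cohort tables is negligible.
#'
#' @param range a [data_range()]; default 1992--2020.
#' @param window_N observation window in years; default 20.
#' @param true_model ground-truth [trend_model()]; default an exponential
#'   trend anchored at 3.0748 years in 1992 with a 93-year doubling time.
#' @param n_per_year diagnoses per calendar year; default 2000, the order of
#'   magnitude of annual kidney-cancer case counts in a multi-registry
#'   surveillance extract.
#' @param noise individual-level noise: `"none"` (every patient gets the
#'   mean), `"gamma"` (shape `noise_param`, right-skewed like cancer
#'   survival), or `"lognormal"` (sdlog `noise_param`).
#' @param noise_param gamma shape or lognormal sigma; default gamma shape 2,
#'   a right-skewed survival distribution whose tail mass beyond a 20-year
#'   window is negligible for means of a few years (keeping the window
#'   truncation bias far below the integer-rounding granularity).
#' @param rounding `"round"` (default), `"floor"`, or `"none"` to keep
#'   real-valued survival times.
#' @param seed integer seed; mandatory when `noise != "none"`.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(range = data_range(1992, 2020),
                              window_N = 20,
                              true_model = trend_model("exponential",
                                                       t0 = 1992, S0 = 3.0748,
                                                       theta = 93),
                              n_per_year = 2000L,
                              noise = c("none", "gamma", "lognormal"),
                              noise_param = 2,
                              rounding = c("round", "floor", "none"),
                              seed = NULL) {
  range <- as_data_range(range)
  noise <- match.arg(noise)
  rounding <- match.arg(rounding)
  stopifnot(window_N >= 1, n_per_year >= 1)
  if (noise != "none" && is.null(seed)) {
    stop("a seed is mandatory for stochastic noise", call. = FALSE)
  }
  yrs <- seq(range$year_min, range$year_max)
  mu <- eval_start(true_model, yrs)
  if (any(mu <= 0 | mu >= window_N)) {
    stop("true trend must stay inside (0, window_N) across the range",
         call. = FALSE)
  }
  structure(list(range = range, window_N = window_N, true_model = true_model,
                 n_per_year = as.integer(n_per_year), noise = noise,
                 noise_param = noise_param, rounding = rounding,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "Simulation: %g-%g, N = %g, %d/yr, noise = %s, rounding = %s\n",
    x$range$year_min, x$range$year_max, x$window_N, x$n_per_year,
    x$noise, x$rounding))
  print(x$true_model)
  invisible(x)
}

# One deterministic substream per diagnosis year, derived from the main seed,
# so adding later years never perturbs earlier years' draws.
year_seed <- function(seed, year, year_min) {
  (as.integer(seed) + 7919L * (as.integer(year) - as.integer(year_min) + 1L)) %%
    2147483647L
}

#' Generate synthetic patient records
#'
#' For each diagnosis year and each of `n_per_year` patients, draws a
#' continuous survival time with mean `eval_start(true_model, year)` under
#' the configured noise model, rounds it per the configuration, and emits the
#' record `(year, year + survival)`. All records are returned, including
#' those whose death year falls beyond the data range or whose survival
#' exceeds the window — exactly the raw material a registry extract would
#' contain; cohort construction applies the eligibility and window rules.
#' Fully reproducible given the seed.
#'
#' @param config a [simulation_config()].
#' @return A `patient_records` data frame with
#'   `nrow = n_years * n_per_year` (aggregated rows carry `count`).
#' @export
simulate_records <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  yrs <- seq(config$range$year_min, config$range$year_max)
  per_year <- lapply(yrs, function(y) {
    mu <- eval_start(config$true_model, y)
    s <- switch(config$noise,
      none = rep(mu, config$n_per_year),
      gamma = {
        set.seed(year_seed(config$seed, y, config$range$year_min))
        stats::rgamma(config$n_per_year, shape = config$noise_param,
                      scale = mu / config$noise_param)
      },
      lognormal = {
        set.seed(year_seed(config$seed, y, config$range$year_min))
        stats::rlnorm(config$n_per_year,
                      meanlog = log(mu) - config$noise_param^2 / 2,
                      sdlog = config$noise_param)
      })
    s <- switch(config$rounding,
                round = round(s), floor = floor(s), none = s)
    data.frame(diagnosis_year = y, death_year = y + s, count = 1)
  })
  out <- do.call(rbind, per_year)
  # aggregate identical (diagnosis, death) pairs for compactness
  agg <- stats::aggregate(count ~ diagnosis_year + death_year, out, sum)
  as_patient_records(agg[order(agg$diagnosis_year, agg$death_year), ])
}

#' Noiseless cohort-table oracle for a simulation configuration
#'
#' Returns the cohort table that [build_cohort_table()] produces from the
#' deterministic records of a `noise = "none"` configuration. With rounding
#' disabled, the start-kind table's means equal the truth curve at the
#' eligible years exactly, and the end-kind means satisfy the end-time
#' transform of the truth model.
#'
#' @param config a [simulation_config()] with `noise = "none"`.
#' @param kind `"start"` or `"end"`.
#' @return A [cohort_table()].
#' @export
expected_cohort_table <- function(config, kind = c("start", "end")) {
  stopifnot(inherits(config, "simulation_config"))
  kind <- match.arg(kind)
  if (config$noise != "none") {
    stop("the cohort-table oracle is defined only for noise = \"none\"",
         call. = FALSE)
  }
  rec <- simulate_records(config)
  build_cohort_table(rec, config$range, config$window_N, kind)
}

#' Write simulated records plus a ground-truth sidecar
#'
#' Writes the records CSV and a JSON sidecar recording the configuration and
#' the true model, for later parameter-recovery scoring.
#'
#' @param config a [simulation_config()].
#' @param path output CSV path; the sidecar is `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(config, path) {
  rec <- simulate_records(config)
  write_records_csv(rec, path)
  sidecar <- list(
    range = c(config$range$year_min, config$range$year_max),
    window_N = config$window_N,
    true_model = model_to_config(config$true_model),
    n_per_year = config$n_per_year,
    noise = config$noise, noise_param = config$noise_param,
    rounding = config$rounding, seed = config$seed)
  jsonlite::write_json(sidecar, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
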