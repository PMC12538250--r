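#' Configuration of the synthetic mortality-data generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' an at-risk cohort observed on a fine age grid between 45 and 86 years,
#' with death counts binomial around a known Heligman-Pollard curve.  The
#' defaults are the study conditions of the package's replication setting:
#' reference parameters as truth, ages 45-86, an initial cohort of
#' 160,000, and a daily grid of roughly 15,000 points that is thinned to
#' quarters before fitting (see [to_quarterly_grid()]).
#'
#' @param true_params Generating [hp_params]; default
#'   [hp_params_reference()].
#' @param age_start,age_end Age window in years; defaults 45 and 86.
#' @param grid `"quarterly"` (default), `"daily"` (step 1/365.25) or
#'   `"annual"`.
#' @param exposure_per_age Binomial denominator per grid age (scalar or
#'   per-age); default `1e4`.
#' @param l0 Initial cohort for trial-like simulation; default 160000.
#' @param seed Integer seed; default 1.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(true_params = hp_params_reference(),
                             age_start = 45, age_end = 86,
                             grid = c("quarterly", "daily", "annual"),
                             exposure_per_age = 1e4, l0 = 160000,
                             seed = 1L) {
  grid <- match.arg(grid)
  true_params <- if (inherits(true_params, "hp_params")) true_params
                 else hp_params(true_params)
  if (age_start <= 0 || age_end <= age_start) {
    stop("need 0 < age_start < age_end")
  }
  if (any(exposure_per_age < 1)) stop("exposure_per_age must be at least 1")
  structure(list(true_params = true_params, age_start = age_start,
                 age_end = age_end, grid = grid,
                 exposure_per_age = exposure_per_age, l0 = l0,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

grid_step <- function(grid) {
  switch(grid, daily = 1 / 365.25, quarterly = 0.25, annual = 1)
}

config_ages <- function(config) {
  seq(config$age_start, config$age_end, by = grid_step(config$grid))
}

#' Simulate an observed mortality schedule
#'
#' Per grid age, draws `deaths ~ Binomial(exposure, q_true(age))` and sets
#' the observed probability to `deaths / exposure`.  Boundary counts (0 or
#' the full exposure), which would put the observed probability outside
#' `(0, 1)`, are nudged inward by half a count; with the default exposures
#' and the reference curve this is never triggered in practice.
#'
#' @param config A [synthetic_config].
#' @param noise_free Return the true curve itself (the infinite-exposure
#'   limit) instead of sampling?  Default `FALSE`.
#' @return A [mortality_schedule]; with noise, its `exposure` and `deaths`
#'   columns are populated.
#' @examples
#' simulate_schedule(synthetic_config(grid = "annual", seed = 42))
#' @export
simulate_schedule <- function(config, noise_free = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  ages <- config_ages(config)
  q_true <- hp_qx(config$true_params, ages, warn_clamp = FALSE)
  if (any(q_true <= 0 | q_true >= 1)) {
    bad <- ages[q_true <= 0 | q_true >= 1][1L]
    stop("true curve leaves (0,1) at age ", bad, "; adjust the configuration")
  }
  if (noise_free) return(mortality_schedule(ages, q_true))
  expo <- round(rep_len(config$exposure_per_age, length(ages)))
  set.seed(config$seed)
  deaths <- stats::rbinom(length(ages), size = expo, prob = q_true)
  deaths <- pmin(pmax(deaths, 0.5), expo - 0.5)
  mortality_schedule(ages, deaths / expo, exposure = expo, deaths = deaths)
}

#' Simulate a trial-like cohort under a policy scenario
#'
#' A stochastic twin of the deterministic life-table recursion: `l0`
#' individuals enter at the delay-shifted diagnosis age and each step
#' kills a `Binomial(alive, q_step)` draw, with `q_step` taken from the
#' same annual probabilities and propagation mode as
#' [propagate_cohort()].  The expected step-deaths equal the deterministic
#' `dx` exactly, which the test suite verifies by Monte Carlo.
#'
#' @param config A [synthetic_config].
#' @param scenario A [policy_scenario]; the cohort starts at
#'   `age_of_diagnosis + policy_delay(scenario)`.
#' @param mode Propagation mode, as in [cohort_from_qx()]; default
#'   `"replication"` to mirror the package's replication setting.
#' @return A list with `trajectory` (a `cohort_trajectory` of integer
#'   counts) and `bands` (per-band death table via [band_cohorts()] with
#'   partial coverage allowed).
#' @export
simulate_trial_like <- function(config, scenario,
                                mode = c("replication", "actuarial")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "synthetic_config"),
            inherits(scenario, "policy_scenario"))
  start_age <- scenario$age_of_diagnosis + policy_delay(scenario)
  if (start_age <= 0 || start_age >= config$age_end) {
    stop("shifted start age ", start_age, " is outside the age window")
  }
  step <- grid_step(config$grid)
  ages <- seq(start_age, config$age_end, by = step)
  q <- hp_qx(config$true_params, ages, warn_clamp = FALSE)
  qs <- if (mode == "replication") q else 1 - (1 - q)^step
  n <- length(ages)
  lx <- numeric(n); dx <- rep(NA_real_, n)
  lx[1L] <- round(config$l0)
  set.seed(config$seed)
  for (i in seq_len(n - 1L)) {
    dx[i] <- stats::rbinom(1L, size = lx[i], prob = min(qs[i], 1))
    lx[i + 1L] <- lx[i] - dx[i]
  }
  tr <- data.frame(age = ages, lx = lx, dx = dx, ex = NA_real_)
  attr(tr, "step") <- step
  attr(tr, "mode") <- mode
  attr(tr, "l0") <- round(config$l0)
  class(tr) <- c("cohort_trajectory", "data.frame")
  tr <- remaining_life_expectancy(tr)
  bands <- band_cohorts(tr, allow_partial = TRUE)
  list(trajectory = tr, bands = bands)
}

#' Multiplicatively perturb an HP parameter set
#'
#' Each parameter is multiplied by `exp(u)`, `u ~ Uniform(-scale, scale)`,
#' so positivity is preserved by construction.  Used to generate starting
#' values for initialisation-robustness checks.
#'
#' @param params An [hp_params].
#' @param relative_scale Perturbation half-width on the log scale, in
#'   `[0, 1)`.
#' @param seed Integer seed.
#' @return A perturbed [hp_params].
#' @examples
#' perturb_params(hp_params_reference(), 0.1, seed = 3)
#' @export
perturb_params <- function(params, relative_scale, seed = 1L) {
  params <- if (inherits(params, "hp_params")) params else hp_params(params)
  if (relative_scale < 0 || relative_scale >= 1) {
    stop("relative_scale must be in [0, 1)")
  }
  set.seed(as.integer(seed))
  hp_params(unclass(params) * exp(stats::runif(8L, -relative_scale,
                                               relative_scale)))
}
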