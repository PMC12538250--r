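#' Economic parameters for productivity costing
#'
#' The human-capital approach values a productive life-year lost at GDP
#' per capita, flat across ages and without discounting; productive years
#' end at the retirement age.
#'
#' @param gdp_per_capita Currency units per person-year; default 17347.
#' @param retirement_age Years; default 67.
#' @param currency Currency label for reports; default `"EUR"`.
#' @return A list of class `"economic_params"`.
#' @export
economic_params <- function(gdp_per_capita = 17347, retirement_age = 67,
                            currency = "EUR") {
  if (!is.numeric(gdp_per_capita) || gdp_per_capita <= 0) {
    stop("gdp_per_capita must be positive")
  }
  if (!is.numeric(retirement_age) || retirement_age <= 0) {
    stop("retirement_age must be positive")
  }
  structure(list(gdp_per_capita = gdp_per_capita,
                 retirement_age = retirement_age,
                 currency = currency),
            class = "economic_params")
}

#' Default five-year age bands
#'
#' The eight five-year bands 45-49, 50-54, ..., 80-84 used for YPPLL
#' grouping of a cohort diagnosed between 45 and 86 (ages 85+ are left out
#' because they cannot form a complete five-year band).
#'
#' @return A data frame with columns `lower` and `upper` (inclusive edges).
#' @export
default_bands <- function() {
  lower <- seq(45, 80, by = 5)
  data.frame(lower = lower, upper = lower + 4)
}

#' Group trajectory deaths into age bands
#'
#' Sums the step-deaths of a cohort trajectory within each band's
#' half-open span `[lower, upper + 1)` and attaches a representative
#' `mean_age` per band, either the death-weighted mean of the grid ages
#' (default -- statistically faithful to where the deaths sit) or the band
#' midpoint `lower + 2.5`.
#'
#' @param trajectory A `cohort_trajectory` from [propagate_cohort()].
#' @param bands A data frame with `lower`/`upper` columns;
#'   default [default_bands()].
#' @param mean_age_rule `"death_weighted"` (default) or `"midpoint"`.
#' @param allow_partial Tolerate bands only partly (or not at all) covered
#'   by the grid, counting the covered deaths?  Default `FALSE`: a band
#'   extending beyond the grid is an error, mirroring the exclusion of
#'   incomplete bands from empirical analyses.
#' @return A data frame of class `"cohort_bands"` with columns `lower`,
#'   `upper`, `deaths`, `mean_age`.
#' @examples
#' tr <- propagate_cohort(hp_params_reference(), 45, 86, step = 0.25,
#'                        l0 = 160000, mode = "replication")
#' band_cohorts(tr)
#' @export
band_cohorts <- function(trajectory, bands = default_bands(),
                         mean_age_rule = c("death_weighted", "midpoint"),
                         allow_partial = FALSE) {
  mean_age_rule <- match.arg(mean_age_rule)
  stopifnot(inherits(trajectory, "cohort_trajectory"))
  step <- attr(trajectory, "step")
  tol <- 1e-9
  ages <- trajectory$age
  dx <- trajectory$dx
  # grid ages that start a step interval
  has_dx <- !is.na(dx)
  covered <- function(lo, hi) {
    # every step interval in [lo, hi + 1) exists on the grid
    lo >= min(ages) - tol && (hi + 1 - step) <= max(ages[has_dx]) + tol
  }
  out <- bands
  out$deaths <- NA_real_
  out$mean_age <- NA_real_
  for (i in seq_len(nrow(bands))) {
    lo <- bands$lower[i]; hi <- bands$upper[i]
    if (!covered(lo, hi) && !allow_partial) {
      stop("band ", lo, "-", hi, " extends beyond the trajectory grid")
    }
    sel <- has_dx & ages >= lo - tol & ages < hi + 1 - tol
    d <- sum(dx[sel])
    out$deaths[i] <- d
    out$mean_age[i] <- if (mean_age_rule == "midpoint") lo + 2.5
      else if (d > 0) sum(dx[sel] * ages[sel]) / d
      else lo + 2.5
  }
  class(out) <- c("cohort_bands", "data.frame")
  out
}

#' Years of life lost (YLL)
#'
#' The premature-mortality burden of a cohort trajectory: each step's
#' deaths weighted by the remaining life expectancy at that age,
#' `YLL = sum(dx * ex)`.  A delay enters upstream, through the
#' delay-shifted trajectory start age.
#'
#' @param trajectory A `cohort_trajectory` with `dx` and `ex` populated.
#' @return Total person-years lost.
#' @examples
#' tr <- propagate_cohort(hp_params_reference(), 45, 86, step = 0.25,
#'                        l0 = 160000, mode = "replication")
#' compute_yll(tr)
#' @export
compute_yll <- function(trajectory) {
  stopifnot(inherits(trajectory, "cohort_trajectory"))
  if (all(is.na(trajectory$ex))) {
    stop("ex is not populated; call remaining_life_expectancy() first")
  }
  sum(trajectory$dx * trajectory$ex, na.rm = TRUE)
}

#' Years of potential productive life lost (YPPLL)
#'
#' Per age band, deaths multiplied by the productive years forgone before
#' retirement, `(retirement_age - mean_age)`.  By default bands whose mean
#' age is at or past the retirement age contribute zero (negative "lost
#' productive years" have no meaning under the human-capital approach);
#' set `truncate = FALSE` for the literal, possibly negative, arithmetic.
#'
#' @param bands A `cohort_bands` data frame from [band_cohorts()] (or any
#'   data frame with `deaths` and `mean_age` columns).
#' @param economics An [economic_params] object.
#' @param truncate Zero out bands past retirement?  Default `TRUE`.
#' @return A list with `by_band` (the input bands plus a `yppll` column)
#'   and `total`.
#' @examples
#' compute_yppll(data.frame(deaths = c(1000, 500), mean_age = c(47, 52)),
#'               economic_params())
#' @export
compute_yppll <- function(bands, economics = economic_params(),
                          truncate = TRUE) {
  stopifnot(inherits(economics, "economic_params"))
  if (nrow(bands) == 0L) {
    warning("empty band list; YPPLL is 0")
    return(list(by_band = bands, total = 0))
  }
  if (any(bands$deaths < 0)) stop("band deaths must be non-negative")
  years <- economics$retirement_age - bands$mean_age
  if (truncate) years <- pmax(years, 0)
  bands$yppll <- bands$deaths * years
  list(by_band = bands, total = sum(bands$yppll))
}

#' Cost of productivity loss (CPL)
#'
#' Values the total productive person-years lost at GDP per capita:
#' `CPL = YPPLL * gdp_per_capita`.
#'
#' @param yppll_total Total productive person-years lost (non-negative).
#' @param economics An [economic_params] object.
#' @return Cost in currency units.
#' @examples
#' compute_cpl(100, economic_params(gdp_per_capita = 1000))
#' @export
compute_cpl <- function(yppll_total, economics = economic_params()) {
  stopifnot(inherits(economics, "economic_params"))
  if (!is.numeric(yppll_total) || yppll_total < 0) {
    stop("yppll_total must be non-negative")
  }
  yppll_total * economics$gdp_per_capita
}

#' Full burden report for one policy scenario
#'
#' Runs the scenario end to end: shifts the cohort start age by the
#' effective delay, propagates survivorship, bands the deaths and computes
#' YLL, YPPLL and CPL.
#'
#' @param params An [hp_params] object.
#' @param scenario A [policy_scenario].
#' @param economics An [economic_params] object.
#' @param end_age Upper end of the propagation grid, years; default 86.
#' @param step Grid step in years; default 0.25.
#' @param l0 Initial cohort; default 160000.
#' @param mode Propagation mode, see [cohort_from_qx()].
#' @param bands Band edges; default [default_bands()].
#' @param mean_age_rule Passed to [band_cohorts()].
#' @param truncate Passed to [compute_yppll()].
#' @param allow_partial_bands Passed to [band_cohorts()]; default `TRUE`
#'   because a shifted start age can leave early bands (harmlessly) empty.
#' @return An object of class `"burden_report"`: a list with `scenario`,
#'   `economics`, `mode`, `start_age`, `yll_total`, `bands` (with per-band
#'   YPPLL), `yppll_total`, `cpl_total` and the `trajectory`.
#' @examples
#' burden_report(hp_params_reference(), policy_scenario(45, delay = 2),
#'               mode = "replication")
#' @export
burden_report <- function(params, scenario, economics = economic_params(),
                          end_age = 86, step = 0.25, l0 = 160000,
                          mode = c("actuarial", "replication"),
                          bands = default_bands(),
                          mean_age_rule = "death_weighted",
                          truncate = TRUE, allow_partial_bands = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(scenario, "policy_scenario"))
  start_age <- scenario$age_of_diagnosis + policy_delay(scenario)
  if (start_age >= end_age) {
    stop("shifted start age (", start_age, ") reaches the end of the grid")
  }
  tr <- propagate_cohort(params, start_age, end_age, step = step, l0 = l0,
                         mode = mode)
  bd <- band_cohorts(tr, bands = bands, mean_age_rule = mean_age_rule,
                     allow_partial = allow_partial_bands)
  yp <- compute_yppll(bd, economics, truncate = truncate)
  out <- list(scenario = scenario, economics = economics, mode = mode,
              start_age = start_age,
              yll_total = compute_yll(tr),
              bands = yp$by_band,
              yppll_total = yp$total,
              cpl_total = compute_cpl(yp$total, economics),
              trajectory = tr)
  class(out) <- "burden_report"
  out
}

#' @export
print.burden_report <- function(x, ...) {
  cat(sprintf(
    "Burden report (%s mode, start age %.4g, delay %.4g y):\n  YLL   %.3f person-years\n  YPPLL %.3f person-years\n  CPL   %.2f %s\n",
    x$mode, x$start_age, policy_delay(x$scenario), x$yll_total,
    x$yppll_total, x$cpl_total, x$economics$currency))
  invisible(x)
}

#' Burden as a function of reimbursement delay
#'
#' Re-runs the full propagate-band-burden pipeline once per delay value
#' (so remaining life expectancy stays consistent with each shifted start
#' age) and returns one [burden_report] per delay.  Delays whose shifted
#' start age falls off the grid produce an error entry; the sweep
#' continues.
#'
#' @inheritParams burden_report
#' @param delays Non-negative delays in years, sorted ascending.
#' @return A list of class `"delay_sweep"`: elements are `burden_report`s
#'   (or `try-error`-like lists with an `error` message for failed
#'   delays), named by delay.
#' @examples
#' sw <- delay_sweep(hp_params_reference(), policy_scenario(45),
#'                   delays = c(0, 1, 2), mode = "replication")
#' as.data.frame(sw)
#' @export
delay_sweep <- function(params, scenario, delays,
                        economics = economic_params(), end_age = 86,
                        step = 0.25, l0 = 160000,
                        mode = c("actuarial", "replication"),
                        bands = default_bands(),
                        mean_age_rule = "death_weighted", truncate = TRUE) {
  mode <- match.arg(mode)
  if (any(delays < 0) || is.unsorted(delays)) {
    stop("delays must be non-negative and sorted ascending")
  }
  out <- lapply(delays, function(d) {
    sc <- policy_scenario(scenario$age_of_diagnosis, delay = d,
                          health_policy = scenario$health_policy)
    tryCatch(
      burden_report(params, sc, economics = economics, end_age = end_age,
                    step = step, l0 = l0, mode = mode, bands = bands,
                    mean_age_rule = mean_age_rule, truncate = truncate),
      error = function(e) structure(list(delay = d, error = conditionMessage(e)),
                                    class = "burden_error"))
  })
  names(out) <- format(delays, trim = TRUE)
  attr(out, "delays") <- delays
  class(out) <- "delay_sweep"
  out
}

#' @export
as.data.frame.delay_sweep <- function(x, ...) {
  rows <- lapply(seq_along(x), function(i) {
    r <- x[[i]]
    d <- attr(x, "delays")[i]
    if (inherits(r, "burden_error")) {
      data.frame(delay = d, metric = "error", value = NA_real_)
    } else {
      data.frame(delay = d,
                 metric = c("yll_total", "yppll_total", "cpl_total"),
                 value = c(r$yll_total, r$yppll_total, r$cpl_total))
    }
  })
  do.call(rbind, rows)
}

#' Write a burden report (JSON and flat CSV)
#'
#' The CSV has one row per band plus a `total` row; the JSON mirrors the
#' report structure without the trajectory.
#'
#' @param report A `burden_report`.
#' @param csv_path,json_path Output files (either may be `NULL`).
#' @param comment Optional provenance comment (CSV header line / JSON
#'   field).
#' @return Invisibly, the paths written.
#' @export
write_burden_report <- function(report, csv_path = NULL, json_path = NULL,
                                comment = NULL) {
  stopifnot(inherits(report, "burden_report"))
  if (!is.null(csv_path)) {
    bands <- as.data.frame(report$bands)
    rows <- data.frame(band = c(paste0(bands$lower, "-", bands$upper), "total"),
                       deaths = c(bands$deaths, sum(bands$deaths)),
                       mean_age = c(bands$mean_age, NA_real_),
                       yppll = c(bands$yppll, report$yppll_total))
    con <- file(csv_path, "w", encoding = "UTF-8")
    if (!is.null(comment)) writeLines(paste0("# ", comment), con)
    utils::write.csv(rows, con, row.names = FALSE)
    close(con)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(comment = comment,
           scenario = unclass(report$scenario),
           economics = unclass(report$economics),
           mode = report$mode, start_age = report$start_age,
           yll_total = report$yll_total,
           yppll_by_band = report$bands$yppll,
           yppll_total = report$yppll_total,
           cpl_total = report$cpl_total),
      json_path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  }
  invisible(c(csv = csv_path, json = json_path))
}
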