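#' Mortality schedule: an age grid with death probabilities
#'
#' The input and output surface of the model fit: a set of strictly
#' increasing positive ages with annual death probabilities `qx` in
#' `(0, 1)`, optionally accompanied by binomial `exposure` counts and
#' observed `deaths` (in which case `qx = deaths / exposure` must hold).
#'
#' @param ages Strictly increasing positive ages, years.
#' @param qx Death probabilities in `(0, 1)`, same length as `ages`.
#' @param exposure Optional positive exposure counts (scalar recycled or
#'   per-age vector).
#' @param deaths Optional non-negative death counts, `deaths <= exposure`.
#' @return A data frame of class `"mortality_schedule"` with columns
#'   `age`, `qx` and, when supplied, `exposure` and `deaths`.
#' @seealso [read_schedule()], [simulate_schedule()], [fit_hp()]
#' @export
mortality_schedule <- function(ages, qx, exposure = NULL, deaths = NULL) {
  if (length(ages) != length(qx)) stop("ages and qx must have equal length")
  if (!is.numeric(ages) || anyNA(ages) || any(ages <= 0)) {
    stop("ages must be positive and non-missing")
  }
  if (is.unsorted(ages, strictly = TRUE)) {
    stop("ages must be strictly increasing (use read_schedule() to normalise order)")
  }
  if (!is.numeric(qx) || anyNA(qx) || any(qx <= 0 | qx >= 1)) {
    bad <- which(is.na(qx) | qx <= 0 | qx >= 1)
    stop("qx must lie strictly in (0, 1); offending rows: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  df <- data.frame(age = as.numeric(ages), qx = as.numeric(qx))
  if (!is.null(exposure)) {
    exposure <- rep_len(as.numeric(exposure), nrow(df))
    if (anyNA(exposure) || any(exposure <= 0)) stop("exposure must be positive")
    df$exposure <- exposure
  }
  if (!is.null(deaths)) {
    if (is.null(exposure)) stop("deaths require exposure")
    deaths <- as.numeric(deaths)
    if (length(deaths) != nrow(df) || anyNA(deaths) || any(deaths < 0)) {
      stop("deaths must be non-negative, one per age")
    }
    if (any(deaths > exposure)) {
      stop("deaths exceed exposure at rows: ",
           paste(utils::head(which(deaths > exposure), 5L), collapse = ", "))
    }
    if (any(abs(df$qx - deaths / exposure) > 1e-12)) {
      stop("qx must equal deaths/exposure (within 1e-12) when both are given")
    }
    df$deaths <- deaths
  }
  class(df) <- c("mortality_schedule", "data.frame")
  df
}

#' @export
print.mortality_schedule <- function(x, ...) {
  cat(sprintf("Mortality schedule: %d ages in [%.4g, %.4g]%s\n",
              nrow(x), min(x$age), max(x$age),
              if (!is.null(x$exposure)) ", with exposures/deaths" else ""))
  print.data.frame(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("...", nrow(x) - 4L, "more rows\n")
  invisible(x)
}

#' Retain the quarterly points of a fine mortality schedule
#'
#' Reduces a fine (at most quarterly, typically daily) age grid to the four
#' quarter points of each whole year covered -- offsets 0, 0.25, 0.5 and
#' 0.75 -- by nearest-grid-point selection.  This mirrors the common
#' practice of fitting an annual-probability mortality law on a quarterly
#' retention of daily measurements.  A year is covered when all four of its
#' quarter offsets fall inside the input age range.
#'
#' @param schedule A [mortality_schedule] whose grid spacing is at most
#'   0.25 years.
#' @return A [mortality_schedule] on the quarter-point grid (ages snapped
#'   to exact quarters; `qx`, `exposure` and `deaths` taken from the
#'   nearest input row).  An already-quarterly input is returned unchanged.
#' @examples
#' daily <- mortality_schedule(45 + (0:400) / 365.25,
#'                             hp_qx(hp_params_reference(), 45 + (0:400) / 365.25))
#' to_quarterly_grid(daily)$age
#' @export
to_quarterly_grid <- function(schedule) {
  stopifnot(inherits(schedule, "mortality_schedule"))
  a <- schedule$age
  if (length(a) < 2L) stop("schedule too short to resample")
  if (max(diff(a)) > 0.25 + 1e-9) {
    stop("input grid spacing exceeds 0.25 years; cannot retain quarters")
  }
  tol <- 1e-9
  years <- seq(ceiling(min(a) - tol), floor(max(a) + tol))
  years <- years[years + 0.75 <= max(a) + tol & years >= min(a) - tol]
  if (length(years) == 0L) stop("input range covers no whole year")
  targets <- as.vector(outer(c(0, 0.25, 0.5, 0.75), years, `+`))
  targets <- sort(targets)
  idx <- vapply(targets, function(t) which.min(abs(a - t)), integer(1))
  out <- as.data.frame(schedule)[idx, , drop = FALSE]
  out$age <- targets
  rownames(out) <- NULL
  mortality_schedule(out$age, out$qx, exposure = out$exposure,
                     deaths = out$deaths)
}
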