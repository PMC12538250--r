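#' Cohort survivorship from annual death probabilities
#'
#' `cohort_from_qx()` runs the life-table recursion
#' `d_x = l_x * q_x`, `l_{x+step} = l_x - d_x`
#' from an initial cohort `l0` along an age grid, given the *annual* death
#' probability attached to each grid age.  Two conventions are supported
#' for sub-annual grids:
#'
#' * `mode = "replication"` applies the annual probability at every step
#'   unadjusted (`d = l * q` per step).  On a quarterly grid this charges
#'   each annual probability four times per year, which collapses the
#'   cohort far faster than the annual law implies; it reproduces a common
#'   (if aggressive) spreadsheet reading of the recursion.
#' * `mode = "actuarial"` converts the annual probability to the step
#'   length first, `q_step = 1 - (1 - q)^step`, which is the
#'   constant-hazard-within-year life-table convention and the default.
#'
#' Ages are interval left endpoints; each grid step covers the half-open
#' interval `[x, x + step)`.
#'
#' `propagate_cohort()` is the usual entry point: it evaluates the HP law
#' on the grid and delegates to `cohort_from_qx()`.
#'
#' @param ages Strictly increasing age grid (years); the last age closes
#'   the final interval and receives no deaths.
#' @param qx Annual death probability at each grid age.
#' @param l0 Initial cohort size at the first age.
#' @param mode `"actuarial"` (default) or `"replication"`, see Details.
#' @param step Grid spacing in years; inferred from `ages` when omitted.
#' @return An object of class `"cohort_trajectory"`: a data frame with
#'   columns `age`, `lx` (survivors at age), `dx` (deaths in `[x, x+step)`;
#'   `NA` at the final age, which starts no interval) and `ex` (remaining
#'   life expectancy, filled in by [remaining_life_expectancy()], which
#'   `propagate_cohort()` calls for you), plus attributes `step`, `mode`
#'   and `l0`.
#' @examples
#' tr <- propagate_cohort(hp_params_reference(), 45, 86, step = 0.25,
#'                        l0 = 160000, mode = "replication")
#' head(tr)
#' @export
cohort_from_qx <- function(ages, qx, l0, mode = c("actuarial", "replication"),
                           step = NULL) {
  mode <- match.arg(mode)
  if (length(ages) < 2L || is.unsorted(ages, strictly = TRUE)) {
    stop("ages must be a strictly increasing grid of length >= 2")
  }
  if (length(qx) != length(ages) || anyNA(qx) || any(qx < 0 | qx > 1)) {
    stop("qx must be probabilities in [0, 1], one per grid age")
  }
  if (!is.numeric(l0) || length(l0) != 1L || l0 <= 0) {
    stop("l0 must be a single positive number")
  }
  if (is.null(step)) step <- diff(ages)[1L]
  n <- length(ages)
  qs <- if (mode == "replication") qx else 1 - (1 - qx)^step
  lx <- numeric(n)
  dx <- rep(NA_real_, n)
  lx[1L] <- l0
  for (i in seq_len(n - 1L)) {
    dx[i] <- lx[i] * qs[i]
    lx[i + 1L] <- lx[i] - dx[i]
  }
  out <- data.frame(age = as.numeric(ages), lx = lx, dx = dx, ex = NA_real_)
  attr(out, "step") <- step
  attr(out, "mode") <- mode
  attr(out, "l0") <- l0
  class(out) <- c("cohort_trajectory", "data.frame")
  remaining_life_expectancy(out)
}

#' @rdname cohort_from_qx
#' @param params An [hp_params] object.
#' @param start_age,end_age Grid limits in years, `start_age > 0`,
#'   `end_age > start_age`.
#' @export
propagate_cohort <- function(params, start_age, end_age, step = 0.25,
                             l0 = 160000,
                             mode = c("actuarial", "replication")) {
  mode <- match.arg(mode)
  if (!is.numeric(start_age) || start_age <= 0) {
    stop("start_age must be strictly positive")
  }
  if (end_age <= start_age) stop("end_age must exceed start_age")
  if (step <= 0) stop("step must be positive")
  ages <- seq(start_age, end_age, by = step)
  if (ages[length(ages)] < end_age - 1e-9) ages <- c(ages, end_age)
  qx <- hp_qx(params, ages, warn_clamp = FALSE)
  cohort_from_qx(ages, qx, l0 = l0, mode = mode, step = step)
}

#' @export
print.cohort_trajectory <- function(x, ...) {
  cat(sprintf(
    "Cohort trajectory (%s mode): %d ages in [%.4g, %.4g], step %.4g y, l0 = %.6g, surviving %.6g\n",
    attr(x, "mode"), nrow(x), min(x$age), max(x$age), attr(x, "step"),
    attr(x, "l0"), x$lx[nrow(x)]))
  print.data.frame(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("...", nrow(x) - 4L, "more rows\n")
  invisible(x)
}

#' Remaining life expectancy along a trajectory
#'
#' Fills the `ex` column of a cohort trajectory with the expected remaining
#' life years at each grid age, computed from the survivorship column as a
#' curtate sum plus a half-interval credit for deaths within an interval:
#' `ex = step * sum_{k > x} l_k / l_x + step / 2`.  At the final grid age
#' the sum is empty and `ex = step / 2` by convention.  Ages where the
#' cohort is extinct (`lx = 0`) get `ex = 0` and are flagged in the
#' `"extinct"` attribute.
#'
#' @param trajectory A `cohort_trajectory` from [cohort_from_qx()].
#' @return The trajectory with `ex` populated.
#' @export
remaining_life_expectancy <- function(trajectory) {
  stopifnot(inherits(trajectory, "cohort_trajectory"))
  step <- attr(trajectory, "step")
  lx <- trajectory$lx
  n <- length(lx)
  tail_l <- rev(cumsum(rev(lx))) - lx    # sum of lx strictly after each index
  ex <- ifelse(lx > 0, step * tail_l / lx + step / 2, 0)
  trajectory$ex <- ex
  attr(trajectory, "extinct") <- lx <= 0
  trajectory
}

#' Deaths at a grid age, optionally aggregated over a whole year
#'
#' Looks up the deaths attached to a trajectory grid age.  With
#' `annual = TRUE` the four (or `1/step`) step-deaths in `[age, age + 1)`
#' are summed, which is how annual death counts are read off a quarterly
#' trajectory.  Off-grid ages are refused rather than interpolated.
#'
#' @param trajectory A `cohort_trajectory`.
#' @param age An age on the trajectory grid.
#' @param annual Sum the step-deaths of the whole year starting at `age`?
#' @return Deaths (a count on the cohort scale).
#' @export
deaths_at_age <- function(trajectory, age, annual = FALSE) {
  stopifnot(inherits(trajectory, "cohort_trajectory"))
  tol <- 1e-9
  i <- which(abs(trajectory$age - age) < tol)
  if (length(i) != 1L) {
    stop("age ", age, " is not on the trajectory grid; interpolation is not performed")
  }
  if (!annual) {
    d <- trajectory$dx[i]
    if (is.na(d)) stop("the final grid age starts no interval and has no deaths")
    return(d)
  }
  in_year <- trajectory$age >= age - tol & trajectory$age < age + 1 - tol
  sum(trajectory$dx[in_year], na.rm = TRUE)
}

#' Write a life-table CSV
#'
#' Columns `age, qx, lx, dx, ex` (period decimal separator, UTF-8); `qx` is
#' the per-step death probability implied by the trajectory
#' (`dx / lx`, `NA` at the final age).
#'
#' @param trajectory A `cohort_trajectory`.
#' @param path Output file.
#' @param comment Optional provenance comment line written above the header.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(trajectory, path, comment = NULL) {
  stopifnot(inherits(trajectory, "cohort_trajectory"))
  df <- data.frame(age = trajectory$age,
                   qx = ifelse(trajectory$lx > 0, trajectory$dx / trajectory$lx,
                               NA_real_),
                   lx = trajectory$lx, dx = trajectory$dx, ex = trajectory$ex)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
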