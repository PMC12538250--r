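#' Evaluate the Heligman-Pollard mortality law
#'
#' Computes the annual death probability
#' \deqn{q_x = A (x+B)^C + D \exp\{-E (\ln x - \ln F)^2\} +
#'       \frac{G H^x}{1 + G H^x},}{q_x = A(x+B)^C + D exp(-E(ln x - ln F)^2)
#'       + G H^x / (1 + G H^x),}
#' the probability that a person of exact age `x` dies before age `x + 1`.
#' The three terms capture, respectively, the decline of childhood
#' mortality, the accident hump of early adulthood, and Gompertz-type
#' senescent mortality.
#'
#' The raw sum of the three terms can exceed 1 at extreme ages; the
#' returned value is clamped at `1 - 1e-12` and a warning is issued when
#' clamping occurs.  Ages are real-valued: the law is routinely evaluated
#' on sub-annual (quarterly or daily) grids.
#'
#' @param params An [hp_params] object.
#' @param x Vector of ages in years; all must be strictly positive (the
#'   hump term involves `log(x)`).
#' @param warn_clamp Warn when the raw sum exceeds 1?  Default `TRUE`.
#' @return `hp_qx()`: a numeric vector of probabilities in `[0, 1]`,
#'   the same length as `x`.  `hp_qx_terms()`: a numeric matrix with one
#'   row per age and columns `childhood`, `hump`, `senescent`; the row sums
#'   equal the unclamped `q_x`.
#' @examples
#' p <- hp_params_reference()
#' hp_qx(p, c(45, 60, 75))
#' hp_qx_terms(p, 45)
#' @export
hp_qx <- function(params, x, warn_clamp = TRUE) {
  q <- rowSums(hp_qx_terms(params, x))
  over <- q > 1
  if (any(over)) {
    if (warn_clamp) {
      warning("raw Heligman-Pollard sum exceeds 1 at ", sum(over),
              " age(s); clamped to 1 - 1e-12")
    }
    q[over] <- 1 - 1e-12
  }
  pmin(pmax(q, 0), 1)
}

#' @rdname hp_qx
#' @export
hp_qx_terms <- function(params, x) {
  params <- if (inherits(params, "hp_params")) params else hp_params(params)
  if (!is.numeric(x) || length(x) == 0L || anyNA(x)) {
    stop("ages must be numeric and non-missing")
  }
  if (any(x <= 0)) stop("ages must be strictly positive")
  A <- params[["A"]]; B <- params[["B"]]; C <- params[["C"]]
  D <- params[["D"]]; E <- params[["E"]]; F <- params[["F"]]
  G <- params[["G"]]; H <- params[["H"]]
  childhood <- A * (x + B)^C
  hump <- D * exp(-E * (log(x) - log(F))^2)
  gh <- G * H^x
  senescent <- gh / (1 + gh)
  cbind(childhood = childhood, hump = hump, senescent = senescent)
}

#' Policy scenario: diagnosis age, reimbursement delay, policy indicator
#'
#' A policy scenario bundles the age at diagnosis, the reimbursement delay
#' (the time between a medicine's marketing authorisation and its
#' reimbursement approval, during which diagnosed patients age without
#' access to the treatment), and a binary health-policy indicator.  When a
#' health policy exists (`health_policy = 1`) the effective delay is zero;
#' the delay only bites in its absence (`health_policy = 0`).
#'
#' Delays are stored internally in years.  Administrative delay data are
#' usually reported in days; pass `delay_unit = "days"` to convert (by
#' 365.25) at the boundary.
#'
#' @param age_of_diagnosis Age at diagnosis, years (non-negative).
#' @param delay Non-negative delay, in `delay_unit`.
#' @param health_policy Either 0 (no policy: the delay applies) or 1
#'   (a policy exists: the effective delay is 0).
#' @param delay_unit `"years"` (default) or `"days"`.
#' @return An object of class `"policy_scenario"`: a list with elements
#'   `age_of_diagnosis`, `delay` (years) and `health_policy`.
#' @examples
#' policy_scenario(45, delay = 548, health_policy = 0, delay_unit = "days")
#' @export
policy_scenario <- function(age_of_diagnosis, delay = 0, health_policy = 0,
                            delay_unit = c("years", "days")) {
  delay_unit <- match.arg(delay_unit)
  if (!is.numeric(age_of_diagnosis) || length(age_of_diagnosis) != 1L ||
      is.na(age_of_diagnosis) || age_of_diagnosis < 0) {
    stop("age_of_diagnosis must be a single non-negative number")
  }
  if (!is.numeric(delay) || length(delay) != 1L || is.na(delay) || delay < 0) {
    stop("delay must be a single non-negative number")
  }
  if (delay_unit == "days") delay <- delay / 365.25
  if (!length(health_policy) == 1L || !health_policy %in% c(0, 1)) {
    stop("health_policy must be 0 (no policy) or 1 (policy exists)")
  }
  structure(list(age_of_diagnosis = as.numeric(age_of_diagnosis),
                 delay = as.numeric(delay),
                 health_policy = as.numeric(health_policy)),
            class = "policy_scenario")
}

#' @export
print.policy_scenario <- function(x, ...) {
  cat(sprintf(
    "Policy scenario: diagnosis at %.4g y, delay %.4g y, health policy %d (effective delay %.4g y)\n",
    x$age_of_diagnosis, x$delay, as.integer(x$health_policy), policy_delay(x)))
  invisible(x)
}

#' Effective delay under a policy scenario
#'
#' Returns the scenario's delay when no health policy exists
#' (`health_policy = 0`) and 0 when one does (`health_policy = 1`).
#'
#' @param scenario A [policy_scenario] object.
#' @return Effective delay in years.
#' @examples
#' policy_delay(policy_scenario(45, delay = 1.5, health_policy = 1)) # 0
#' @export
policy_delay <- function(scenario) {
  stopifnot(inherits(scenario, "policy_scenario"))
  if (scenario$health_policy == 1) 0 else scenario$delay
}

#' Delay-shifted death probability
#'
#' Evaluates the HP law at the delay-shifted age
#' `x = age_of_diagnosis + effective delay`: the death probability faced by
#' a patient whose access to treatment is postponed by the scenario's
#' effective delay.
#'
#' @inheritParams hp_qx
#' @param scenario A [policy_scenario] object.
#' @return Annual death probability at the shifted age.
#' @examples
#' p <- hp_params_reference()
#' shifted_qx(p, policy_scenario(45, delay = 5))   # = hp_qx(p, 50)
#' @export
shifted_qx <- function(params, scenario, warn_clamp = TRUE) {
  stopifnot(inherits(scenario, "policy_scenario"))
  x <- scenario$age_of_diagnosis + policy_delay(scenario)
  hp_qx(params, x, warn_clamp = warn_clamp)
}
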