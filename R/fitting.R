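#' The eight predefined loss functions
#'
#' Heligman-Pollard fitting minimises one of eight predefined objectives
#' comparing the observed death probabilities `q` with the model values
#' `qhat` (and, for the count-based deviances, observed deaths `d` against
#' expected deaths `n * qhat`):
#'
#' 1. `relative_sse` -- `sum((1 - qhat/q)^2)`, the classic HP relative
#'    squared error and the package default;
#' 2. `absolute_sse` -- `sum((q - qhat)^2)`;
#' 3. `log_sse` -- `sum((log(q) - log(qhat))^2)`;
#' 4. `pearson_sse` -- `sum((q - qhat)^2 / qhat)`;
#' 5. `binomial_deviance` -- the binomial deviance of observed deaths
#'    against `n * qhat` (requires `deaths` and `exposure`);
#' 6. `poisson_deviance` -- the Poisson deviance of observed deaths against
#'    `n * qhat` (requires `deaths` and `exposure`);
#' 7. `absolute_error` -- `sum(|q - qhat|)`;
#' 8. `relative_error` -- `sum(|1 - qhat/q|)`.
#'
#' Losses 1-6 have a residual (sum-of-squares) form and are minimised by
#' Levenberg-Marquardt; 7 and 8 fall back to Nelder-Mead.
#'
#' @return `hp_loss_names()`: the eight registered identifiers, in the
#'   order above.
#' @export
hp_loss_names <- function() names(hp_loss_registry)

loss_residuals <- list(
  relative_sse = function(q, qhat, d, n) 1 - qhat / q,
  absolute_sse = function(q, qhat, d, n) q - qhat,
  log_sse = function(q, qhat, d, n) log(q) - log(qhat),
  pearson_sse = function(q, qhat, d, n) (q - qhat) / sqrt(qhat),
  binomial_deviance = function(q, qhat, d, n) {
    e <- n * qhat
    t1 <- ifelse(d > 0, d * log(d / e), 0)
    t2 <- ifelse(n - d > 0, (n - d) * log((n - d) / (n - e)), 0)
    sign(d - e) * sqrt(pmax(2 * (t1 + t2), 0))
  },
  poisson_deviance = function(q, qhat, d, n) {
    e <- n * qhat
    t1 <- ifelse(d > 0, d * log(d / e), 0)
    sign(d - e) * sqrt(pmax(2 * (t1 - (d - e)), 0))
  }
)

hp_loss_registry <- c(
  lapply(loss_residuals, function(r) {
    function(q, qhat, d = NULL, n = NULL) sum(r(q, qhat, d, n)^2)
  }),
  list(
    absolute_error = function(q, qhat, d = NULL, n = NULL) sum(abs(q - qhat)),
    relative_error = function(q, qhat, d = NULL, n = NULL) sum(abs(1 - qhat / q))
  )
)

loss_needs_counts <- c("binomial_deviance", "poisson_deviance")

# derivative of each residual w.r.t. qhat, for the analytic Jacobian
# (the count-based deviance residuals fall back to numeric differentiation)
loss_dresid_dqhat <- list(
  relative_sse = function(q, qhat, d, n) -1 / q,
  absolute_sse = function(q, qhat, d, n) rep(-1, length(q)),
  log_sse = function(q, qhat, d, n) -1 / qhat,
  pearson_sse = function(q, qhat, d, n) {
    -1 / sqrt(qhat) - (q - qhat) / (2 * qhat^1.5)
  }
)

# Jacobian of q_x w.r.t. the working parameters (log A..G, log(H-1)),
# one row per age, ignoring the (essentially never active) clamp at 1
hp_qx_jacobian_working <- function(params, x) {
  A <- params[["A"]]; B <- params[["B"]]; C <- params[["C"]]
  D <- params[["D"]]; E <- params[["E"]]; F <- params[["F"]]
  G <- params[["G"]]; H <- params[["H"]]
  u <- log(x) - log(F)
  eu <- exp(-E * u^2)
  gh <- G * H^x
  den2 <- (1 + gh)^2
  xb <- x + B
  cbind(
    A = A * xb^C,                        # d q / d log A
    B = B * A * C * xb^(C - 1),
    C = C * A * xb^C * log(xb),
    D = D * eu,
    E = E * (-D * u^2 * eu),
    F = F * (D * eu * 2 * E * u / F),
    G = G * (H^x / den2),
    H = (H - 1) * (G * x * H^(x - 1) / den2)
  )
}

#' Evaluate a loss at a parameter set
#'
#' @param loss One of [hp_loss_names()].
#' @param observed A [mortality_schedule]; the count-based losses require
#'   its `deaths` and `exposure` columns.
#' @param params An [hp_params] object.
#' @return The non-negative objective value.
#' @examples
#' sched <- mortality_schedule(c(50, 60, 70), c(0.05, 0.1, 0.2))
#' loss_value("relative_sse", sched, hp_params_reference())
#' @export
loss_value <- function(loss, observed, params) {
  loss <- match.arg(loss, hp_loss_names())
  stopifnot(inherits(observed, "mortality_schedule"))
  fn <- hp_loss_registry[[loss]]
  if (loss %in% loss_needs_counts &&
      (is.null(observed$deaths) || is.null(observed$exposure))) {
    stop("loss '", loss, "' requires deaths and exposure columns")
  }
  qhat <- hp_qx(params, observed$age, warn_clamp = FALSE)
  fn(observed$qx, qhat, observed$deaths, observed$exposure)
}

# Unconstrained working scale: log for A..G, log(H - 1) for H, so that
# positivity (and H > 1) hold by construction and box bounds map cleanly.
hp_to_working <- function(p) {
  c(log(pmax(unclass(p)[1:7], 1e-300)), log(max(p[["H"]] - 1, 1e-300)))
}
hp_from_working <- function(theta) {
  hp_params(c(exp(theta[1:7]), 1 + exp(theta[8])))
}

default_hp_bounds <- function() {
  lower <- c(rep(1e-12, 7), 1 + 1e-12)
  upper <- c(1e6, 1e6, 200, 1e6, 1e6, 1e6, 1e6, 2)
  names(lower) <- names(upper) <- hp_param_names
  list(lower = lower, upper = upper)
}

#' Fit the Heligman-Pollard law to a mortality schedule
#'
#' Estimates the eight HP parameters by minimising one of the predefined
#' losses (see [hp_loss_names()]).  Optimisation is a bounded local search
#' from `init` on a log scale (`log(H - 1)` for `H`), which enforces
#' positivity by construction: Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]) for the six residual-form losses, Nelder-Mead
#' with an L-BFGS-B polish for the two absolute-error losses.  The HP
#' objectives are multimodal, so a sensible start matters; the default is
#' the reference parameter set, which suits schedules on the 45-86 window.
#'
#' Note the parameters of the childhood and hump terms are weakly
#' identified when the schedule only covers older ages (their terms are
#' orders of magnitude below the senescent term there); the fitted curve
#' and the senescent parameters `G`, `H` are what such data determine.
#'
#' @param observed A [mortality_schedule] with at least 9 ages.
#' @param loss One of [hp_loss_names()]; default `"relative_sse"`.
#' @param init Starting [hp_params]; default [hp_params_reference()].
#' @param lower,upper Optional named per-parameter bounds (natural scale).
#'   Defaults: all parameters in `[1e-12, 1e6]` except `C` in
#'   `[1e-12, 200]` and `H` in `(1, 2]`.
#' @param control List of optimiser settings: `ftol` (relative objective
#'   tolerance, default `1e-10`) and `maxfev` (maximum objective
#'   evaluations, default `1e5`).
#' @return An object of class `"hp_fit"`: a list with elements `params`,
#'   `loss`, `loss_value`, `init_loss_value`, `fitted_qx`, `observed`,
#'   `converged`, `n_obs`, `df` (`n_obs - 8`), and -- when the schedule
#'   carries deaths and exposures -- `deviance`, `gof_pvalue` from
#'   [deviance_gof()].
#' @examples
#' sched <- simulate_schedule(synthetic_config(grid = "quarterly", seed = 1))
#' fit <- fit_hp(sched)
#' fit$params
#' @export
fit_hp <- function(observed, loss = "relative_sse",
                   init = hp_params_reference(),
                   lower = NULL, upper = NULL, control = list()) {
  loss <- match.arg(loss, hp_loss_names())
  stopifnot(inherits(observed, "mortality_schedule"))
  n <- nrow(observed)
  if (n < 9L) stop("fitting 8 parameters requires at least 9 observations")
  if (loss %in% loss_needs_counts &&
      (is.null(observed$deaths) || is.null(observed$exposure))) {
    stop("loss '", loss, "' requires deaths and exposure columns")
  }
  init <- if (inherits(init, "hp_params")) init else hp_params(init)
  b <- default_hp_bounds()
  if (!is.null(lower)) b$lower[names(lower)] <- lower
  if (!is.null(upper)) b$upper[names(upper)] <- upper
  # a start outside the box (e.g. a perturbed H dipping below 1) is
  # projected onto it rather than rejected

  ftol <- control$ftol %||% 1e-10
  maxfev <- control$maxfev %||% 1e5

  ages <- observed$age
  q <- observed$qx
  d <- observed$deaths
  expo <- observed$exposure

  theta0 <- hp_to_working(init)
  lw <- hp_to_working(hp_params(pmax(b$lower, 1e-300)))
  up <- hp_to_working(hp_params(b$upper))
  theta0 <- pmin(pmax(theta0, lw), up)
  # optimisers may probe non-finite trial points; map them back into the box
  safe_params <- function(theta) {
    theta[!is.finite(theta)] <- theta0[!is.finite(theta)]
    hp_from_working(pmin(pmax(theta, lw), up))
  }
  qhat_of <- function(theta) hp_qx(safe_params(theta), ages, warn_clamp = FALSE)
  obj <- function(theta) hp_loss_registry[[loss]](q, qhat_of(theta), d, expo)

  converged <- FALSE
  if (!is.null(loss_residuals[[loss]])) {
    rfun <- loss_residuals[[loss]]
    jfun <- NULL
    if (!is.null(loss_dresid_dqhat[[loss]])) {
      dr <- loss_dresid_dqhat[[loss]]
      jfun <- function(theta) {
        p <- safe_params(theta)
        qhat <- hp_qx(p, ages, warn_clamp = FALSE)
        J <- dr(q, qhat, d, expo) * hp_qx_jacobian_working(p, ages)
        # extreme corners of the box can overflow the childhood term;
        # freezing the offending direction keeps the search finite
        J[!is.finite(J)] <- 0
        J
      }
    }
    ctl <- minpack.lm::nls.lm.control(
      ftol = ftol, ptol = 1e-10, maxfev = as.integer(min(maxfev, 1e5)),
      maxiter = as.integer(control$maxiter %||% 1024L))
    lmfit <- function(start) minpack.lm::nls.lm(
      par = start, fn = function(theta) rfun(q, qhat_of(theta), d, expo),
      jac = jfun, lower = lw, upper = up, control = ctl)
    res <- lmfit(theta0)
    theta <- res$par
    if (any(!is.finite(theta))) theta <- theta0
    converged <- res$info %in% 1:4
    # the iteration cap can be hit while crawling along the flat valley of
    # the weakly identified childhood/hump parameters; warm restarts reset
    # the damping and terminate properly, or reveal genuine stagnation
    tries <- 0L
    while (!converged && tries < 4L) {
      res2 <- lmfit(theta)
      if (any(!is.finite(res2$par))) break
      old <- obj(theta)
      improve <- (old - obj(res2$par)) / max(old, 1e-300)
      theta <- res2$par
      converged <- res2$info %in% 1:4 || improve <= 1e-7
      tries <- tries + 1L
    }
  } else {
    res <- stats::optim(theta0, obj, method = "Nelder-Mead",
                        control = list(maxit = maxfev, reltol = ftol))
    polish <- tryCatch(
      stats::optim(res$par, obj, method = "L-BFGS-B", lower = lw, upper = up,
                   control = list(factr = 1e4)),
      error = function(e) res)
    theta <- if (polish$value <= res$value) polish$par else res$par
    theta <- pmin(pmax(theta, lw), up)
    converged <- res$convergence == 0
  }

  init_loss <- obj(theta0)
  final_loss <- obj(theta)
  if (!is.finite(final_loss) || final_loss > init_loss) {
    # a failed search never beats its own start
    theta <- theta0
    final_loss <- init_loss
    converged <- FALSE
  }
  params <- safe_params(theta)
  fitted_qx <- hp_qx(params, ages, warn_clamp = FALSE)

  out <- list(params = params, loss = loss, loss_value = final_loss,
              init_loss_value = init_loss, fitted_qx = fitted_qx,
              observed = observed, converged = converged,
              n_obs = n, df = n - 8L,
              deviance = NA_real_, gof_pvalue = NA_real_)
  if (!is.null(d) && !is.null(expo)) {
    g <- deviance_gof(d, expo, fitted_qx)
    out$deviance <- g$deviance
    out$gof_pvalue <- g$p_value
  }
  class(out) <- "hp_fit"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hp_fit <- function(x, ...) {
  cat(sprintf("Heligman-Pollard fit (loss '%s', %d ages, %sconverged)\n",
              x$loss, x$n_obs, if (x$converged) "" else "NOT "))
  print(x$params)
  cat(sprintf("objective: %.6g (from %.6g at start)\n",
              x$loss_value, x$init_loss_value))
  if (is.finite(x$deviance)) {
    cat(sprintf("deviance GOF: %.4f on %d df, p = %.4g\n",
                x$deviance, x$df, x$gof_pvalue))
  }
  invisible(x)
}

#' Binomial deviance goodness-of-fit test
#'
#' Likelihood-ratio comparison of the fitted binomial model against the
#' saturated model:
#' `D = 2 * sum(d * log(d/e) + (n - d) * log((n - d)/(n - e)))` with
#' `e = n * qhat` and the convention `0 * log(0/x) = 0`, referred to a
#' chi-square distribution on `length(d) - n_params` degrees of freedom.
#' A fitted probability of exactly 0 or 1 that disagrees with the counts
#' yields an infinite deviance (and p = 0).
#'
#' @param deaths Observed death counts per age.
#' @param exposure Binomial denominators per age, `deaths <= exposure`.
#' @param fitted_qx Fitted probabilities in `(0, 1)` (0/1 tolerated only
#'   where the counts agree exactly).
#' @param n_params Number of estimated parameters (default 8).
#' @return A list with `deviance`, `df` and `p_value`.
#' @examples
#' deviance_gof(deaths = c(5, 8), exposure = c(100, 100),
#'              fitted_qx = c(0.05, 0.08), n_params = 0)
#' @export
deviance_gof <- function(deaths, exposure, fitted_qx, n_params = 8L) {
  k <- length(deaths)
  if (length(exposure) != k || length(fitted_qx) != k) {
    stop("deaths, exposure and fitted_qx must have equal length")
  }
  if (any(deaths < 0) || any(deaths > exposure)) {
    stop("deaths must satisfy 0 <= deaths <= exposure")
  }
  e <- exposure * fitted_qx
  t1 <- ifelse(deaths > 0, deaths * log(deaths / e), 0)
  t2 <- ifelse(exposure - deaths > 0,
               (exposure - deaths) * log((exposure - deaths) / (exposure - e)),
               0)
  D <- 2 * sum(t1 + t2)
  if (is.nan(D)) D <- Inf
  D <- max(D, 0)
  df <- k - n_params
  p <- if (df >= 1) stats::pchisq(D, df, lower.tail = FALSE) else NA_real_
  if (df >= 1 && !is.finite(D)) p <- 0
  list(deviance = D, df = df, p_value = p)
}

#' Bootstrap confidence intervals and p-values for an HP fit
#'
#' Parametric bootstrap: deaths are redrawn at each age as
#' `Binomial(exposure, qhat)` from the point fit, the observed
#' probabilities recomputed, and the model refitted from the same start
#' as the point fit, so every replicate is treated exactly like the
#' original data (warm-starting refits at the point estimate would fail
#' to explore the trade-off between the senescent slope and the weakly
#' identified childhood term, and understate the uncertainty of `H`).
#' Per-parameter 95% confidence intervals use the
#' percentile method.  P-values are two-sided tests of `H0: parameter = 0`
#' inverted from the *basic* (reflected) bootstrap interval -- the smallest
#' level at which that interval excludes 0, i.e.
#' `p = min(1, 2 * mean(replicate >= 2 * estimate))`, floored at
#' `1 / (n_replicates + 1)`.  (Percentile intervals of a
#' positivity-constrained parameter can never cross 0, so they cannot be
#' inverted for this test.)
#'
#' A nonparametric alternative (`scheme = "nonparametric"`) resamples ages
#' (rows) with replacement instead of redrawing counts.
#'
#' Replicate fits that fail to converge are dropped and counted; more than
#' 20% failures is an error.
#'
#' @inheritParams fit_hp
#' @param observed A [mortality_schedule] with `exposure` (and, for the
#'   count-based losses, `deaths`).
#' @param n_replicates Number of bootstrap replicates, at least 100.
#' @param seed Integer seed; the whole procedure is reproducible given it.
#' @param scheme `"parametric"` (default) or `"nonparametric"`.
#' @param level Confidence level, default 0.95.
#' @return An object of class `"hp_bootstrap"`: a list with `replicates`
#'   (matrix, one row per successful replicate, columns `A`...`H`),
#'   `estimate`, `ci_low`, `ci_high`, `p_values`, `n_replicates`,
#'   `n_failed`, `seed`, `level` and the point `fit`.
#' @examples
#' \donttest{
#' sched <- simulate_schedule(synthetic_config(grid = "annual",
#'                                             exposure_per_age = 1e5,
#'                                             seed = 7))
#' bootstrap_fit(sched, n_replicates = 100, seed = 7)
#' }
#' @export
bootstrap_fit <- function(observed, loss = "relative_sse",
                          n_replicates = 200L, seed = 1L,
                          scheme = c("parametric", "nonparametric"),
                          init = hp_params_reference(), level = 0.95,
                          control = list()) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(observed, "mortality_schedule"))
  if (n_replicates < 100L) stop("n_replicates must be at least 100")
  if (scheme == "parametric" && is.null(observed$exposure)) {
    stop("the parametric scheme requires exposure counts")
  }
  fit <- fit_hp(observed, loss = loss, init = init, control = control)
  qhat <- fit$fitted_qx
  n_age <- nrow(observed)
  set.seed(as.integer(seed))
  reps <- matrix(NA_real_, n_replicates, 8L,
                 dimnames = list(NULL, hp_param_names))
  failed <- 0L
  for (b in seq_len(n_replicates)) {
    sched_b <- tryCatch({
      if (scheme == "parametric") {
        expo <- observed$exposure
        d_b <- stats::rbinom(n_age, size = round(expo), prob = qhat)
        d_b <- pmin(pmax(d_b, 0.5), round(expo) - 0.5) # keep q in (0,1)
        mortality_schedule(observed$age, d_b / round(expo),
                           exposure = round(expo), deaths = d_b)
      } else {
        idx <- sort(unique(sample.int(n_age, n_age, replace = TRUE)))
        if (length(idx) < 9L) stop("degenerate resample")
        mortality_schedule(observed$age[idx], observed$qx[idx],
                           exposure = observed$exposure[idx],
                           deaths = observed$deaths[idx])
      }
    }, error = function(e) NULL)
    fit_b <- if (is.null(sched_b)) NULL else tryCatch(
      fit_hp(sched_b, loss = loss, init = init, control = control),
      error = function(e) NULL)
    if (is.null(fit_b) || !fit_b$converged) {
      failed <- failed + 1L
    } else {
      reps[b, ] <- unclass(fit_b$params)
    }
  }
  if (failed > 0.2 * n_replicates) {
    stop(failed, " of ", n_replicates, " bootstrap refits failed (> 20%)")
  }
  reps <- reps[stats::complete.cases(reps), , drop = FALSE]
  alpha <- 1 - level
  ci <- apply(reps, 2L, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  est <- unclass(fit$params)
  pv <- vapply(hp_param_names, function(nm) {
    p <- 2 * mean(reps[, nm] >= 2 * est[[nm]])
    max(min(p, 1), 1 / (nrow(reps) + 1))
  }, numeric(1))
  structure(list(replicates = reps, estimate = est,
                 ci_low = ci[1L, ], ci_high = ci[2L, ],
                 p_values = pv, n_replicates = nrow(reps),
                 n_failed = failed, seed = as.integer(seed),
                 level = level, scheme = scheme, fit = fit),
            class = "hp_bootstrap")
}

#' @export
print.hp_bootstrap <- function(x, ...) {
  cat(sprintf("HP %s bootstrap: %d replicates (%d failed), %.0f%% percentile CIs\n",
              x$scheme, x$n_replicates, x$n_failed, 100 * x$level))
  print(data.frame(estimate = x$estimate, ci_low = x$ci_low,
                   ci_high = x$ci_high, p_value = x$p_values,
                   row.names = hp_param_names), digits = 5)
  invisible(x)
}

#' Write a fit report as JSON
#'
#' Serialises the point estimates, objective, deviance test and (when
#' given) the bootstrap CI table to a JSON file.
#'
#' @param fit An `hp_fit`.
#' @param path Output file.
#' @param bootstrap Optional `hp_bootstrap` for the CI table.
#' @param comment Optional provenance string stored under `"comment"`.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, bootstrap = NULL, comment = NULL) {
  stopifnot(inherits(fit, "hp_fit"))
  rep <- list(comment = comment,
              loss = fit$loss,
              params = as.list(unclass(fit$params)),
              loss_value = fit$loss_value,
              converged = fit$converged,
              n_obs = fit$n_obs, df = fit$df,
              deviance = fit$deviance, gof_pvalue = fit$gof_pvalue)
  if (!is.null(bootstrap)) {
    rep$bootstrap <- list(
      n_replicates = bootstrap$n_replicates,
      level = bootstrap$level, scheme = bootstrap$scheme,
      seed = bootstrap$seed,
      ci_low = as.list(bootstrap$ci_low),
      ci_high = as.list(bootstrap$ci_high),
      p_values = as.list(bootstrap$p_values))
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
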