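test_that("exactly eight losses are registered and behave as residual sums", {
  expect_length(hp_loss_names(), 8L)
  sched <- simulate_schedule(synthetic_config(grid = "quarterly"),
                             noise_free = TRUE)
  # a perfectly reproduced schedule has zero loss under every pure residual sum
  for (l in c("relative_sse", "absolute_sse", "log_sse", "pearson_sse",
              "absolute_error", "relative_error")) {
    expect_equal(loss_value(l, sched, ref_params), 0, tolerance = 1e-20,
                 label = l)
  }
})

test_that("losses evaluate to hand-computed values on toy schedules", {
  one <- mortality_schedule(50, 0.2)
  # fitted value at a single age engineered to be 0.1: q = A * x with A = 0.002
  p <- hp_params(A = 0.002, B = 0, C = 1, D = 0, E = 1, F = 1, G = 0, H = 1.05)
  expect_equal(loss_value("absolute_sse", one, p), 0.01)
  toy <- mortality_schedule(c(50, 60, 70), c(0.05, 0.10, 0.20))
  expect_equal(loss_value("relative_sse", toy, ref_params),
               oracle_toy_rel_sse, tolerance = 1e-12)
})

test_that("count-based losses demand death counts", {
  sched <- mortality_schedule(45:60, hp_qx(ref_params, 45:60))
  expect_error(loss_value("binomial_deviance", sched, ref_params), "requires")
  expect_error(fit_hp(sched, loss = "poisson_deviance"), "requires")
})

test_that("fitting refuses underdetermined schedules and never worsens the start", {
  small <- mortality_schedule(45:52, hp_qx(ref_params, 45:52))
  expect_error(fit_hp(small), "at least 9")
  sched <- simulate_schedule(synthetic_config(grid = "annual",
                                              exposure_per_age = 1e4,
                                              seed = 21))
  for (l in c("relative_sse", "log_sse", "absolute_error")) {
    init <- perturb_params(ref_params, 0.05, seed = 5)
    f <- suppressWarnings(fit_hp(sched, loss = l, init = init))
    expect_lte(f$loss_value, f$init_loss_value)
    expect_equal(f$loss_value, loss_value(l, sched, f$params),
                 tolerance = 1e-12)
  }
})

test_that("a noise-free schedule is recovered from a perturbed start", {
  sched <- simulate_schedule(synthetic_config(grid = "quarterly"),
                             noise_free = TRUE)
  init <- perturb_params(ref_params, 0.1, seed = 11)
  f <- suppressWarnings(fit_hp(sched, init = init))
  expect_true(f$converged)
  expect_lt(max(abs(f$fitted_qx / sched$qx - 1)), 1e-4)
  expect_lt(abs(f$params[["G"]] / ref_params[["G"]] - 1), 0.01)
  expect_lt(abs(f$params[["H"]] / ref_params[["H"]] - 1), 0.01)
})

test_that("a flat featureless schedule still yields a finite converged fit", {
  flat <- mortality_schedule(seq(40, 48), rep(0.5, 9))
  f <- suppressWarnings(fit_hp(flat))
  expect_true(is.finite(f$loss_value))
  expect_s3_class(f$params, "hp_params")
})

test_that("the binomial deviance is zero at saturated agreement and additive-order invariant", {
  n <- rep(1000, 12)
  qhat <- seq(0.05, 0.16, by = 0.01)
  d <- n * qhat                       # expected counts hit exactly
  g <- deviance_gof(d, n, qhat)
  expect_equal(g$deviance, 0)
  expect_identical(g$df, 4L)
  expect_equal(g$p_value, 1)
  expect_equal(deviance_gof(5, 10, 0.5, n_params = 0)$deviance, 0)
  # permutation of ages leaves the statistic unchanged
  set.seed(4)
  d2 <- rbinom(12, 1000, qhat)
  perm <- sample(12)
  expect_equal(deviance_gof(d2, n, qhat)$deviance,
               deviance_gof(d2[perm], n[perm], qhat[perm])$deviance)
  # a fitted probability of 1 contradicted by survivors blows up honestly
  g_inf <- deviance_gof(c(3, rep(50, 9)), rep(100, 10), c(1, rep(0.5, 9)))
  expect_true(is.infinite(g_inf$deviance))
  expect_equal(g_inf$p_value, 0)
  expect_error(deviance_gof(11, 10, 0.5), "deaths")
})

test_that("the deviance GOF tracks chi-square expectations on simulated counts", {
  ages <- 45:64
  q_true <- hp_qx(ref_params, ages)
  set.seed(8)
  n <- 1e5
  d <- rbinom(length(ages), n, q_true)
  g <- deviance_gof(d, rep(n, length(ages)), q_true, n_params = 0)
  # with the true curve, D ~ chi-square(20): far tails are implausible
  expect_gt(g$deviance, qchisq(0.0005, 20))
  expect_lt(g$deviance, qchisq(0.9995, 20))
})

test_that("the parametric bootstrap is deterministic under a fixed seed", {
  sched <- simulate_schedule(synthetic_config(grid = "annual",
                                              age_end = 66,
                                              exposure_per_age = 1e5,
                                              seed = 31))
  b1 <- suppressWarnings(bootstrap_fit(sched, n_replicates = 100, seed = 9,
                                       control = list(ftol = 1e-8)))
  b2 <- suppressWarnings(bootstrap_fit(sched, n_replicates = 100, seed = 9,
                                       control = list(ftol = 1e-8)))
  expect_identical(b1$replicates, b2$replicates)
  expect_identical(b1$ci_low, b2$ci_low)
  expect_error(bootstrap_fit(sched, n_replicates = 50, seed = 1),
               "at least 100")
})

test_that("bootstrap intervals bracket the point estimate and cover the truth at large exposure", {
  sched <- simulate_schedule(synthetic_config(grid = "annual",
                                              exposure_per_age = 1e6,
                                              seed = 13))
  b <- suppressWarnings(bootstrap_fit(sched, n_replicates = 100, seed = 13,
                                      control = list(ftol = 1e-8)))
  # bracketing of the point estimate is only meaningful for parameters the
  # data identify; those of the vanishing childhood/hump terms wander over
  # orders of magnitude between equally good fits
  for (nm in c("A", "G", "H")) {
    expect_lte(b$ci_low[[nm]], b$estimate[[nm]])
    expect_gte(b$ci_high[[nm]], b$estimate[[nm]])
  }
  expect_true(all(b$p_values >= 0 & b$p_values <= 1))
  # the well-identified senescent parameters are inside their intervals
  expect_true(b$ci_low[["G"]] <= ref_params[["G"]] &&
              ref_params[["G"]] <= b$ci_high[["G"]])
  expect_true(b$ci_low[["H"]] <= ref_params[["H"]] &&
              ref_params[["H"]] <= b$ci_high[["H"]])
})

test_that("bootstrap intervals tighten as exposure grows tenfold", {
  widths <- sapply(c(1e4, 1e5), function(expo) {
    sched <- simulate_schedule(synthetic_config(grid = "annual",
                                                exposure_per_age = expo,
                                                seed = 17))
    b <- suppressWarnings(bootstrap_fit(sched, n_replicates = 100, seed = 17,
                                        control = list(ftol = 1e-8)))
    b$ci_high - b$ci_low
  })
  # median width across the eight parameters strictly decreases
  expect_lt(stats::median(widths[, 2]), stats::median(widths[, 1]))
  expect_lt(widths["H", 2], widths["H", 1])
})
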