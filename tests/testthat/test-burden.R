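test_that("YLL is the expectancy-weighted death sum", {
  tr <- make_traj(age = c(60, 61, 62), lx = c(15, 5, 0),
                  dx = c(10, 5, NA), ex = c(30, 20, 0.5))
  expect_equal(compute_yll(tr), 10 * 30 + 5 * 20)
  none <- make_traj(age = c(60, 61), lx = c(10, 10), dx = c(0, NA),
                    ex = c(2, 1))
  expect_equal(compute_yll(none), 0)
  bare <- make_traj(age = c(60, 61), lx = c(10, 10), dx = c(0, NA),
                    ex = c(NA_real_, NA_real_))
  expect_error(compute_yll(bare), "remaining_life_expectancy")
})

test_that("YPPLL counts productive years with truncation at retirement", {
  eco <- economic_params()
  one <- data.frame(deaths = 100, mean_age = 50)
  expect_equal(compute_yppll(one, eco)$total, 1700)
  old <- data.frame(deaths = 100, mean_age = 70)
  expect_equal(compute_yppll(old, eco)$total, 0)
  expect_equal(compute_yppll(old, eco, truncate = FALSE)$total, -300)
  two <- data.frame(deaths = c(1000, 500), mean_age = c(47, 52))
  expect_equal(compute_yppll(two, eco)$total, 27500)
  expect_warning(res <- compute_yppll(two[0, ], eco), "empty")
  expect_equal(res$total, 0)
})

test_that("YPPLL is monotone non-decreasing in the retirement age", {
  bands <- data.frame(deaths = c(1000, 500, 200),
                      mean_age = c(47.5, 62.5, 72.5))
  totals <- vapply(c(55, 60, 65, 67, 70, 75), function(r) {
    compute_yppll(bands, economic_params(retirement_age = r))$total
  }, numeric(1))
  expect_true(all(diff(totals) >= 0))
})

test_that("CPL is YPPLL valued at GDP per capita, exactly", {
  expect_equal(compute_cpl(100, economic_params(gdp_per_capita = 1000)),
               100000)
  expect_equal(compute_cpl(0, economic_params(gdp_per_capita = 123)), 0)
  rep <- burden_report(ref_params, policy_scenario(45), mode = "replication")
  expect_identical(rep$cpl_total / rep$economics$gdp_per_capita,
                   rep$yppll_total)
})

test_that("banding groups deaths on half-open five-year spans", {
  # one death at each whole age 45..49, nothing elsewhere
  tr <- make_traj(age = 45:51, lx = 7:1, dx = c(rep(1, 5), 0, NA),
                  ex = rep(1, 7))
  b <- band_cohorts(tr, bands = data.frame(lower = 45, upper = 49),
                    mean_age_rule = "midpoint")
  expect_equal(b$deaths, 5)
  expect_equal(b$mean_age, 47.5)
  # all deaths concentrated at age 46: the death-weighted mean sits there
  tr2 <- make_traj(age = 45:50, lx = c(9, 9, 3, 3, 3, 3),
                   dx = c(0, 6, 0, 0, 0, NA), ex = rep(1, 6))
  b2 <- band_cohorts(tr2, bands = data.frame(lower = 45, upper = 49))
  expect_equal(b2$mean_age, 46)
  expect_error(band_cohorts(tr2, bands = data.frame(lower = 48, upper = 52)),
               "beyond the trajectory grid")
  expect_silent(band_cohorts(tr2, bands = data.frame(lower = 48, upper = 52),
                             allow_partial = TRUE))
})

test_that("the default banding covers 45-84 in eight five-year bands", {
  b <- default_bands()
  expect_identical(nrow(b), 8L)
  expect_equal(b$lower, seq(45, 80, by = 5))
  expect_equal(b$upper - b$lower, rep(4, 8))
  tr <- propagate_cohort(ref_params, 45, 86, step = 0.25, l0 = 160000,
                         mode = "replication")
  bd <- band_cohorts(tr)
  expect_true(all(bd$mean_age >= bd$lower & bd$mean_age <= bd$upper + 1))
  expect_lte(sum(bd$deaths), 160000)
})

test_that("burden totals scale linearly in the initial cohort", {
  r1 <- burden_report(ref_params, policy_scenario(45, delay = 1),
                      l0 = 160000, mode = "replication")
  r2 <- burden_report(ref_params, policy_scenario(45, delay = 1),
                      l0 = 320000, mode = "replication")
  expect_equal(r2$yll_total, 2 * r1$yll_total, tolerance = 1e-12)
  expect_equal(r2$yppll_total, 2 * r1$yppll_total, tolerance = 1e-12)
  expect_equal(r2$cpl_total, 2 * r1$cpl_total, tolerance = 1e-12)
})

test_that("the delay sweep is deterministic and collapses under a policy", {
  sw_pol <- delay_sweep(ref_params, policy_scenario(45, health_policy = 1),
                        delays = c(0, 3), mode = "replication")
  expect_equal(sw_pol[[1]]$yll_total, sw_pol[[2]]$yll_total)
  sw <- delay_sweep(ref_params, policy_scenario(45), delays = c(2, 2, 2),
                    mode = "replication")
  expect_equal(sw[[1]]$yll_total, sw[[3]]$yll_total)
  expect_equal(sw[[1]]$cpl_total, sw[[2]]$cpl_total)
  df <- as.data.frame(sw)
  expect_identical(nrow(df), 9L)
  expect_identical(unique(df$metric),
                   c("yll_total", "yppll_total", "cpl_total"))
  # an impossible shifted start age yields an error entry, not an abort
  sw_bad <- delay_sweep(ref_params, policy_scenario(45),
                        delays = c(0, 50), mode = "replication")
  expect_s3_class(sw_bad[[2]], "burden_error")
  expect_false(inherits(sw_bad[[1]], "burden_error"))
})

test_that("first-year deaths after diagnosis grow with the delay", {
  d_first <- vapply(seq(0, 20, by = 2), function(d) {
    tr <- propagate_cohort(ref_params, 45 + d, 86, step = 0.25,
                           l0 = 160000, mode = "replication")
    deaths_at_age(tr, 45 + d, annual = TRUE)
  }, numeric(1))
  expect_true(all(diff(d_first) > 0))
})
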