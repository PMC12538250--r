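test_that("constant mortality decays the cohort geometrically", {
  tr <- cohort_from_qx(0:3, rep(0.1, 4), l0 = 100, mode = "replication")
  expect_equal(tr$lx, c(100, 90, 81, 72.9))
  expect_equal(tr$dx, c(10, 9, 8.1, NA))
  expect_equal(deaths_at_age(tr, 0), 10)
})

test_that("zero and total mortality give flat and extinguished cohorts", {
  flat <- cohort_from_qx(1:5, rep(0, 5), l0 = 42)
  expect_true(all(flat$lx == 42))
  expect_true(all(flat$dx[1:4] == 0))
  gone <- cohort_from_qx(1:5, c(1, 1, 1, 1, 1), l0 = 7, mode = "replication")
  expect_equal(deaths_at_age(gone, 1), 7)
  expect_true(all(gone$lx[-1] == 0))
  expect_true(all(gone$dx[2:4] == 0))
})

test_that("survivorship conserves the initial cohort and never increases", {
  tr <- propagate_cohort(ref_params, 45, 86, step = 0.25, l0 = 160000,
                         mode = "replication")
  expect_true(all(diff(tr$lx) <= 0))
  expect_true(all(tr$lx >= 0))
  expect_equal(tr$lx[1] - tr$lx[nrow(tr)], sum(tr$dx, na.rm = TRUE),
               tolerance = 1e-9)
  expect_lte(sum(tr$dx, na.rm = TRUE), 160000)
  expect_error(propagate_cohort(ref_params, 50, 45), "exceed")
})

test_that("actuarial sub-annual steps reproduce annual survivorship for year-constant q", {
  q_year <- hp_qx(ref_params, 45:55)
  annual <- cohort_from_qx(45:55, q_year, l0 = 1000, mode = "actuarial",
                           step = 1)
  ages_q <- seq(45, 55, by = 0.25)
  quarterly <- cohort_from_qx(ages_q, q_year[floor(ages_q) - 44],
                              l0 = 1000, mode = "actuarial", step = 0.25)
  at_whole <- quarterly$lx[ages_q %% 1 == 0]
  expect_equal(at_whole, annual$lx, tolerance = 1e-12)
})

test_that("replication mode kills faster than actuarial mode on sub-annual grids", {
  rep_tr <- propagate_cohort(ref_params, 45, 86, step = 0.25, l0 = 1,
                             mode = "replication")
  act_tr <- propagate_cohort(ref_params, 45, 86, step = 0.25, l0 = 1,
                             mode = "actuarial")
  expect_true(all(rep_tr$lx[-1] < act_tr$lx[-1]))
})

test_that("remaining life expectancy follows the curtate-plus-half convention", {
  # death certain within the first interval: half an interval of credit
  gone <- cohort_from_qx(1:4, rep(1, 4), l0 = 10, mode = "replication")
  expect_equal(gone$ex[1], 0.5)
  expect_true(all(gone$ex[-1] == 0))
  expect_true(any(attr(gone, "extinct")))
  # guaranteed survival for 10 years then certain death
  sure <- cohort_from_qx(0:11, c(rep(0, 10), 1, 1), l0 = 5,
                         mode = "replication")
  expect_equal(sure$ex[1], 10.5)
  # constant q = 0.5 approaches the geometric closed form (1-q)/q + 1/2
  const <- cohort_from_qx(1:61, rep(0.5, 61), l0 = 1, mode = "replication")
  expect_equal(const$ex[1], 0.5 / 0.5 + 0.5, tolerance = 1e-12)
  # strictly decreasing along an increasing mortality curve
  tr <- propagate_cohort(ref_params, 45, 86, step = 0.25, l0 = 160000,
                         mode = "actuarial")
  expect_true(all(diff(tr$ex) < 0))
})

test_that("deaths look up only on-grid ages, with annual aggregation", {
  tr <- propagate_cohort(ref_params, 45, 86, step = 0.25, l0 = 160000,
                         mode = "replication")
  expect_error(deaths_at_age(tr, 45.1), "not on the trajectory grid")
  expect_error(deaths_at_age(tr, 86), "no deaths")
  d46 <- sum(tr$dx[tr$age >= 46 & tr$age < 47])
  expect_equal(deaths_at_age(tr, 46, annual = TRUE), d46)
  # annual sums regrouped in fives equal the band deaths (independent path)
  annual_deaths <- vapply(45:84, function(a) deaths_at_age(tr, a, annual = TRUE),
                          numeric(1))
  bands <- band_cohorts(tr)
  expect_equal(bands$deaths,
               as.numeric(tapply(annual_deaths, rep(1:8, each = 5), sum)))
})

test_that("quarterly retention keeps exactly four points per whole year", {
  p <- ref_params
  daily_1y <- mortality_schedule(seq(45, 46, by = 1 / 365.25),
                                 hp_qx(p, seq(45, 46, by = 1 / 365.25)))
  q1 <- to_quarterly_grid(daily_1y)
  expect_equal(q1$age, c(45, 45.25, 45.5, 45.75))

  ages_daily <- seq(45, 86, by = 1 / 365.25)     # ~15,000 daily measurements
  daily <- mortality_schedule(ages_daily, hp_qx(p, ages_daily))
  qq <- to_quarterly_grid(daily)
  expect_identical(nrow(qq), 164L)               # 41 whole years x 4 quarters
  expect_equal(qq$age[1:4], c(45, 45.25, 45.5, 45.75))
  expect_equal(max(qq$age), 85.75)

  quarterly <- mortality_schedule(seq(45, 49.75, by = 0.25),
                                  hp_qx(p, seq(45, 49.75, by = 0.25)))
  expect_equal(as.data.frame(to_quarterly_grid(quarterly)),
               as.data.frame(quarterly))
  coarse <- mortality_schedule(45:50, hp_qx(p, 45:50))
  expect_error(to_quarterly_grid(coarse), "spacing")
})

test_that("life tables serialise with the documented columns", {
  tr <- propagate_cohort(ref_params, 45, 50, step = 1, l0 = 100)
  path <- withr::local_tempfile(fileext = ".csv")
  write_life_table(tr, path, comment = "cfg abc")
  first <- readLines(path, n = 1)
  expect_match(first, "^# cfg abc")
  df <- utils::read.csv(path, comment.char = "#")
  expect_identical(names(df), c("age", "qx", "lx", "dx", "ex"))
  expect_equal(df$lx, tr$lx)
})
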