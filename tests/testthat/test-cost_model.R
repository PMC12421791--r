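test_that("FTE retirement trajectory follows the declared schedule", {
  p <- cost_parameters()
  expect_equal(fte_multiplier(65, p), 0.9)
  expect_equal(fte_multiplier(71, p), 0.9)
  expect_equal(fte_multiplier(c(72, 73, 74, 75), p), c(0.8, 0.7, 0.6, 0.5))
  expect_equal(fte_multiplier(76, p), 0)
  expect_equal(fte_multiplier(90, p), 0)
  expect_equal(fte_multiplier(10, p), 0)  # below labour-entry age
  expect_error(fte_multiplier(-1, p), "age")
  ages <- 16:100
  expect_true(all(diff(fte_multiplier(ages, p)) <= 0))
})

test_that("PV of future earnings matches a year-by-year oracle and limits", {
  p <- cost_parameters()
  lt <- default_life_table()
  es <- default_earnings_schedule()
  # age 80: FTE is zero over the whole remaining horizon
  expect_equal(pv_future_earnings(list(age = 80, sex = "male",
                                       occupation_code = "1211"),
                                  lt, es, p), 0)
  # zero discount + flat FTE 1.0 over an H-year horizon reduces to S * H
  flat <- cost_parameters(discount_rate = 0, fte_entry_age = 0,
                          fte_full = 1,
                          fte_taper = c(`72` = 1, `73` = 1, `74` = 1,
                                        `75` = 1))
  lt10 <- data.frame(age = 0:120, male = 10, female = 10)
  es_flat <- list(by_code = c(`1` = 60000), default_earnings = 60000)
  expect_equal(pv_future_earnings(list(age = 30, sex = "male",
                                       occupation_code = NA),
                                  lt10, es_flat, flat),
               60000 * 10)
  # mid-career case against the independent straight loop
  kase <- list(age = 40, sex = "male", occupation_code = NA, year = 2023,
               work_related = "non_work")
  wage <- 60000
  es60 <- list(by_code = c(`x` = 1), default_earnings = wage)
  horizon <- ceiling(lt$male[lt$age == 40])
  expected <- 0
  for (t in seq_len(horizon)) {
    a <- 40 + t
    f <- if (a <= 71) 0.9 else if (a >= 76) 0
         else c(`72` = 0.8, `73` = 0.7, `74` = 0.6, `75` = 0.5)[[as.character(a)]]
    expected <- expected + wage * f / 1.03^t
  }
  expect_equal(pv_future_earnings(kase, lt, es60, p), expected)
})

test_that("household production respects the sex-specific windows", {
  p <- cost_parameters()
  expect_equal(pv_household_production(list(age = 77, sex = "male"), p), 0)
  expect_equal(pv_household_production(list(age = 76, sex = "male"), p), 0)
  p0 <- cost_parameters(discount_rate = 0)
  expect_equal(pv_household_production(list(age = 81, sex = "female"), p0),
               p0$hp_annual_value)  # one remaining year, undiscounted
  # a child accrues nothing before 16: oracle loop from 16 to the end age
  expected <- sum(p$hp_annual_value / 1.03^((16:76) - 10))
  expect_equal(pv_household_production(list(age = 10, sex = "male"), p),
               expected)
  # women accrue six more years than men at the same age
  m <- pv_household_production(list(age = 50, sex = "male"), p0)
  f <- pv_household_production(list(age = 50, sex = "female"), p0)
  expect_equal(f - m, 6 * p0$hp_annual_value)
})

test_that("friction cost is the configured fraction of salary", {
  p <- cost_parameters()
  expect_equal(friction_cost(80000, p), 20000)
  expect_equal(friction_cost(0, p), 0)
  expect_equal(friction_cost(61000, p), 15250)
  expect_error(friction_cost(-1, p), "salary")
})

test_that("CPI indexation is a ratio with identity and inverse", {
  cpi <- c(`2013` = 100, `2023` = 130)
  expect_equal(index_to_base_year(1000, 2013, cpi), 1300)
  expect_equal(index_to_base_year(555, 2023, cpi), 555)
  back <- index_to_base_year(1000, 2013, cpi) *
    cpi[["2013"]] / cpi[["2023"]]
  expect_equal(back, 1000, tolerance = 1e-9)
  expect_error(index_to_base_year(1, 1999, cpi), "1999")
})

test_that("case costs agree with the independent straight-loop oracle", {
  p <- cost_parameters()
  lt <- default_life_table()
  es <- default_earnings_schedule()
  cpi <- default_cpi()
  cases <- random_cases(200, seed = 42)
  t0 <- Sys.time()
  for (i in seq_len(nrow(cases))) {
    kase <- as.list(cases[i, ])
    b <- case_cost(kase, lt, es, cpi, p)
    expect_equal(b$total, oracle_case_cost(kase, lt, es, cpi, p),
                 tolerance = 1e-9)
    expect_equal(b$total, sum(b$components), tolerance = 1e-9)
    expect_true(all(b$components >= 0))
  }
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 30)
})

test_that("compensation enters only for work-related deaths", {
  base <- list(age = 50, sex = "male", year = 2023,
               occupation_code = "1211")
  p <- cost_parameters()
  work <- case_cost(c(base, work_related = "work"), params = p)
  nonwork <- case_cost(c(base, work_related = "non_work"), params = p)
  expect_equal(work$components[["compensation"]], p$compensation_payout)
  expect_equal(nonwork$components[["compensation"]], 0)
  expect_equal(work$total - nonwork$total, p$compensation_payout)
})

test_that("zeroed parameters give a zero total", {
  p0 <- cost_parameters(friction_fraction = 0, hp_annual_value = 0,
                        fixed_costs = c(funeral = 0), compensation_payout = 0,
                        fte_full = 0,
                        fte_taper = c(`72` = 0, `73` = 0, `74` = 0, `75` = 0))
  b <- case_cost(list(age = 40, sex = "male", year = 2023,
                      work_related = "work", occupation_code = "1211"),
                 params = p0)
  expect_equal(b$total, 0)
})

test_that("PV of future earnings is non-increasing in age at death", {
  p <- cost_parameters()
  lt <- default_life_table()
  es <- default_earnings_schedule()
  pv <- vapply(16:95, function(a)
    pv_future_earnings(list(age = a, sex = "male",
                            occupation_code = "1211"), lt, es, p),
    numeric(1))
  expect_true(all(diff(pv) <= 1e-9))
})

test_that("doubling the household-production value doubles only that component", {
  kase <- list(age = 45, sex = "female", year = 2023,
               work_related = "work", occupation_code = "1211")
  b1 <- case_cost(kase, params = cost_parameters())
  b2 <- case_cost(kase, params = cost_parameters(hp_annual_value = 50000))
  expect_equal(b2$components[["household_production"]],
               2 * b1$components[["household_production"]])
  other <- setdiff(names(b1$components), "household_production")
  expect_equal(b2$components[other], b1$components[other])
})

test_that("annualisation and coverage adjustment follow the conventions", {
  expect_equal(annualise(1.8e9, 11, multiple = 1e6), 164e6)
  expect_equal(annualise(1.24e9, 11, multiple = 1e6), 113e6)
  expect_equal(annualise(0, 5), 0)
  expect_error(annualise(1, 0), "n_years")
  p <- cost_parameters()
  expect_equal(adjust_for_coverage(190, p, multiple = 5), 265)
  expect_equal(adjust_for_coverage(100, cost_parameters(under_coverage_factor = 0)),
               100)
  expect_equal(adjust_for_coverage(190, p, convention = "coverage"),
               190 / 0.58)
})
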