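test_that("cost per life-year divides cost by life-years, to the rand", {
  expect_equal(cost_per_life_year(96399102, 36134), 2668)
  expect_equal(cost_per_life_year(96399102, 53278), 1809)
  expect_equal(cost_per_life_year(96399102, 17854), 5399)
  expect_error(cost_per_life_year(100, 0), "> 0")
})

test_that("threshold effectiveness solves the closed form and is linear in cost", {
  # constructed identity: benchmark chosen so e = 1
  deaths <- c(10, 20); lyl <- c(30, 25)
  bench <- 1000 / sum(deaths * lyl)
  expect_equal(threshold_effectiveness(1000, deaths, lyl, bench), 1)
  expect_equal(threshold_effectiveness(2000, deaths, lyl, bench), 2)
  # Waterberg scenario: near 0.6% of uniform effectiveness at the GDP
  # benchmark and 0.75% at the household-income benchmark
  wb <- waterberg_fixture()$conditions
  lyl_wb <- wb$life_years_saved / wb$lives_saved
  e_gdp <- threshold_effectiveness(96399102, wb$baseline_deaths, lyl_wb,
                                   99169)
  expect_equal(e_gdp, 0.006, tolerance = 0.01)
  e_inc <- threshold_effectiveness(96399102, wb$baseline_deaths, lyl_wb,
                                   79524)
  expect_equal(e_inc, 0.0075, tolerance = 0.01)
  expect_error(threshold_effectiveness(100, deaths, lyl, 0), "benchmark")
  expect_error(threshold_effectiveness(100, c(0, 0), lyl, 10), "> 0")
})

test_that("discounted earnings PV matches the hand-computed annuity", {
  # 10000/1.1 + 10000/1.21 = 17 355.37
  expect_equal(discounted_earnings_pv(10000, 2, 0.10), 17355.37,
               tolerance = 1e-6)
  expect_equal(discounted_earnings_pv(10000, 3, 0), 30000)
  expect_equal(discounted_earnings_pv(10000, 0, 0.05), 0)
  expect_error(discounted_earnings_pv(10000, -1, 0.05), "years")
})

test_that("PV decreases in the discount rate and increases in horizon", {
  pv <- vapply(c(0.0072, 0.03, 0.06),
               function(r) discounted_earnings_pv(50000, 30, r), numeric(1))
  expect_true(all(diff(pv) < 0))  # 0.72% > 3% > 6% ordering
  horizons <- vapply(c(5, 15, 30, 45),
                     function(y) discounted_earnings_pv(50000, y, 0.03),
                     numeric(1))
  expect_true(all(diff(horizons) > 0))
})

test_that("benefit perspectives net income as documented", {
  p <- copc_params()
  pov <- net_annual_income(perspective = "poverty_reduction", params = p)
  expect_equal(pov, p$avg_household_income * p$unemployment_adjustment *
                 (1 - p$tax_rate))
  gdp <- net_annual_income(perspective = "gdp", params = p)
  expect_equal(gdp, p$avg_household_income * p$unemployment_adjustment -
                 p$schooling_cost - p$child_grant)
})

test_that("HIV/TB treatment savings follow multiplier x fraction x base", {
  expect_equal(round(hivtb_treatment_savings(), 1), 39.4)  # 2.2 x 0.203 x 88.3
  expect_equal(hivtb_treatment_savings(
    copc_params(hivtb_saving_multiplier = 0)), 0)
  # linear in each parameter
  expect_equal(hivtb_treatment_savings(copc_params(hivtb_cost_base = 176.6)),
               2 * hivtb_treatment_savings())
})

test_that("health-system savings price utilisation deltas at unit costs", {
  deltas <- c(clinic_visits = 110664, admissions = 4729, opd_visits = 23646)
  expect_equal(health_system_savings(
    deltas, c(clinic_visits = 0, admissions = 0, opd_visits = 0)), 0)
  # calibrated defaults reproduce the R120m planning figure
  expect_equal(health_system_savings(deltas) / 1e6, 120, tolerance = 0.001)
  expect_equal(health_system_savings(2 * deltas),
               2 * health_system_savings(deltas))
  expect_error(health_system_savings(c(clinic_visits = 1)), "admissions")
})

test_that("wage injection sums the community staff lines of the ledger", {
  l <- build_ledger()
  expect_equal(wages_injection(l), 51.6)  # 27 015 933 + 5 030 067 + 19 551 511
  expect_equal(wages_injection(l, include = c("CHW FTE", "TL")), 46.6)
  expect_error(wages_injection(l, include = "Nurses"), "missing staff")
  d <- waterberg_demand()
  d$by_class$total_cspc <- 0; d$total_cspc <- 0
  l0 <- build_ledger(plan = size_workforce(d))
  expect_equal(wages_injection(l0), 0)
})

test_that("benefit-to-cost ratio is a one-decimal quotient, scale-invariant", {
  expect_equal(benefit_cost_ratio(330e6, 96399102), 3.4)
  expect_equal(benefit_cost_ratio(100, 100), 1.0)
  expect_equal(benefit_cost_ratio(0, 100), 0.0)
  expect_equal(benefit_cost_ratio(3 * 330e6, 3 * 96399102), 3.4)
  expect_error(benefit_cost_ratio(100, 0), "total_cost")
})

test_that("cost per life-year at the three bounds orders inversely to life-years", {
  wb <- waterberg_fixture()
  l <- build_ledger()
  cpl <- cost_per_life_year(l$overall_total,
                            wb$impact_reference$life_years)
  # upper effectiveness -> most life-years -> cheapest
  expect_equal(unname(cpl[c("upper", "expected", "lower")]),
               c(1809, 2668, 5399))
  expect_true(all(diff(cpl[c("upper", "expected", "lower")]) > 0))
})
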