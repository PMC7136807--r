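test_that("default parameters carry the 2019 planning values", {
  p <- copc_params()
  expect_equal(p$chw_monthly_wage, 3500)
  expect_equal(p$hourly_wage, 20)
  expect_equal(p$tax_rate, 0.18)
  expect_equal(p$life_expectancy, 60)
  expect_equal(unname(p$minutes_per_cspc), c(28, 28, 30))
  expect_equal(p$gdp_per_capita, 99169)
})

test_that("overrides pass through and invalid values are rejected", {
  expect_equal(copc_params(life_expectancy = 65)$life_expectancy, 65)
  expect_error(copc_params(tax_rate = 1.5), "fraction")
  expect_error(copc_params(chw_monthly_wage = -1), "non-negative")
  expect_error(copc_params(nonsense = 1), "unknown parameter")
  expect_error(copc_params(proximal_distance_km = 0), "proximal_distance_km")
})

test_that("YAML config loading: empty config gives defaults, overrides apply", {
  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", empty)
  loaded <- load_params(empty)
  expect_equal(loaded$params$chw_monthly_wage, 3500)
  expect_equal(loaded$params$tax_rate, 0.18)
  expect_equal(loaded$params$life_expectancy, 60)

  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("params:", "  life_expectancy: 65"), cfg)
  loaded <- load_params(cfg)
  expect_equal(loaded$params$life_expectancy, 65)
  expect_equal(loaded$params$chw_monthly_wage, 3500)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("params:", "  tax_rate: 1.5"), bad)
  expect_error(load_params(bad), "tax_rate")
  expect_error(load_params("no/such/file.yaml"), "not found")
})

test_that("params round-trip through save and load unchanged", {
  p <- copc_params(life_expectancy = 62, tax_rate = 0.2,
                   minutes_per_cspc = c(proximal = 25, distal = 27,
                                        remote = 31))
  path <- withr::local_tempfile(fileext = ".yaml")
  save_params(p, path)
  p2 <- load_params(path)$params
  expect_equal(unclass(p2), unclass(p))
})

test_that("default condition profiles match the planning effectiveness table", {
  cp <- default_condition_profiles()
  expect_equal(nrow(cp), 7)
  expect_setequal(cp$condition_id,
                  c("maternal_neonatal", "infant", "child", "hiv", "tb",
                    "ncd", "acute"))
  expect_false(anyDuplicated(cp$condition_id) > 0)
  hiv <- cp[cp$condition_id == "hiv", ]
  expect_equal(c(hiv$eff_lower, hiv$eff_expected, hiv$eff_upper),
               c(0.18, 0.37, 0.55))
  ncd <- cp[cp$condition_id == "ncd", ]
  expect_equal(c(ncd$eff_lower, ncd$eff_expected, ncd$eff_upper),
               c(0.06, 0.12, 0.18))
  expect_true(all(cp$eff_lower <= cp$eff_expected &
                    cp$eff_expected <= cp$eff_upper))
  expect_true(all(cp$mortality_per_1000 >= 0))
  expect_true(all(cp$mean_age < copc_params()$life_expectancy))
})

test_that("quintile mortality ratios follow the stated poorest:richest gaps", {
  cp <- default_condition_profiles()
  r <- setNames(cp$mortality_ratio, cp$condition_id)
  expect_equal(unname(r["maternal_neonatal"]), 5.9)
  expect_equal(unname(r["child"]), 4.9)
  expect_equal(unname(r["tb"]), 9.1)
  expect_equal(unname(r["hiv"]), 2.78)
  # NCD: prevalence-weighted mean of diabetes 3.3 and cardiovascular 2.3
  expect_equal(unname(r["ncd"]), 0.17 * 3.3 + 0.83 * 2.3)
  expect_equal(unname(r["acute"]), 2.78)
})

test_that("condition profiles round-trip through CSV", {
  cp <- default_condition_profiles()
  path <- withr::local_tempfile(fileext = ".csv")
  write_condition_profiles(cp, path)
  header <- readLines(path, n = 1)
  expect_equal(header,
    "condition_id,contacts_per_affected_year,mortality_per_1000,mean_age,eff_lower,eff_expected,eff_upper,mortality_ratio")
  cp2 <- read_condition_profiles(path)
  cols <- c("condition_id", "contacts_per_affected_year",
            "mortality_per_1000", "mean_age", "eff_lower", "eff_expected",
            "eff_upper", "mortality_ratio")
  expect_equal(cp2[, cols], cp[, cols])
})
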