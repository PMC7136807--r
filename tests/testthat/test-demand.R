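test_that("quintile thresholds use 20/40/60/80th percentiles with lower-side ties", {
  q <- compute_quintiles(1:100)
  expect_equal(q$thresholds, c(20.8, 40.6, 60.4, 80.2))
  expect_equal(q$counts, rep(20, 5))
  # degenerate: all incomes equal -> everyone in Q1
  qd <- compute_quintiles(rep(1000, 50))
  expect_equal(qd$counts, c(50, 0, 0, 0, 0))
  expect_error(compute_quintiles(1:4), "at least 5")
})

test_that("lognormal sample splits into exact fifths (sort-and-split oracle)", {
  set.seed(123)
  inc <- rlnorm(10000, 10, 1)
  q <- compute_quintiles(inc)
  expect_equal(q$counts, rep(2000, 5))
  # oracle: sorting and splitting into 5 blocks gives the same membership
  oracle <- rep(1:5, each = 2000)[rank(inc, ties.method = "first")]
  expect_equal(q$quintile, oracle)
})

test_that("eligible population excludes Q5 households", {
  areas <- make_areas(lat = c(0, 0.1), lon = c(0, 0.1),
                      population = c(400, 600),
                      households = c(50, 200))
  # area 1 holds exactly the richest fifth of households (Q5)
  hh <- data.frame(
    area_id = rep(c("T001", "T002"), c(50, 200)),
    income = c(201:250, 1:200))
  qs <- compute_quintiles(hh$income)
  mix <- area_quintile_mix(hh, qs)
  expect_equal(eligible_population(areas[1, , drop = FALSE], mix), 0)
  expect_equal(eligible_population(areas[2, , drop = FALSE], mix), 600)
  # uniform incomes: 80% of the population remains eligible
  set.seed(4)
  hh_u <- data.frame(area_id = rep("T001", 1000), income = runif(1000))
  mix_u <- area_quintile_mix(hh_u, compute_quintiles(hh_u$income))
  a1 <- make_areas(lat = 0, lon = 0, population = 1000, households = 1000)
  expect_equal(eligible_population(a1, mix_u), 800)
  # NULL mix means the layer is already net of Q5
  expect_equal(eligible_population(areas), 1000)
})

test_that("quintile mortality gradient preserves the mean and the Q1:Q5 ratio", {
  # identity when ratio is 1
  expect_equal(unname(adjust_mortality_by_quintile(10, 1)), rep(10, 5))
  # hand-solved linear system: rates r1 * (1 - (q-1)/4 * (1 - 1/R)),
  # rescaled so the equal-weight mean is the base rate
  base <- 10; R <- 9.1
  shape <- 1 - (0:4) / 4 * (1 - 1 / R)
  expected <- base * shape / mean(shape)
  got <- adjust_mortality_by_quintile(base, R)
  expect_equal(unname(got), expected)
  expect_equal(got[["Q1"]] / got[["Q5"]], R)
  expect_equal(sum(0.2 * got), base, tolerance = 1e-9)
  # property: mean preserved for random weights, ratios and both gradients
  set.seed(21)
  for (i in 1:20) {
    w <- runif(5); w <- w / sum(w)
    R <- runif(1, 1, 10); b <- runif(1, 0.1, 50)
    g <- sample(c("linear", "geometric"), 1)
    r <- adjust_mortality_by_quintile(b, R, w, gradient = g)
    expect_equal(sum(w * r), b, tolerance = 1e-9)
    expect_equal(r[["Q1"]] / r[["Q5"]], R, tolerance = 1e-9)
    expect_true(all(diff(r) <= 1e-12))  # poorest quintile has highest rate
  }
  expect_error(adjust_mortality_by_quintile(10, 0.5), "ratio")
})

test_that("computed demand responds monotonically to contact rates", {
  pop <- generate_small_areas(60, 3, seed = 3)
  cc <- aggregate_catchments(pop$areas,
                             assign_nearest_facility(pop$areas,
                                                     pop$facilities))
  mix <- area_quintile_mix(pop$households,
                           compute_quintiles(pop$households$income))
  cp <- default_condition_profiles()
  d0 <- compute_demand(cc, cp, quintile_mix = mix)
  cp2 <- cp
  cp2$contacts_per_affected_year[cp2$condition_id == "hiv"] <-
    cp2$contacts_per_affected_year[cp2$condition_id == "hiv"] + 1
  d1 <- compute_demand(cc, cp2, quintile_mix = mix)
  expect_gt(d1$total_cspc, d0$total_cspc)
  # only the HIV row changed
  unchanged <- d0$by_condition$condition_id != "hiv"
  expect_equal(d1$by_condition$cspc[unchanged],
               d0$by_condition$cspc[unchanged])
})

test_that("risk adjustment raises demand for poor catchments, not death totals", {
  pop <- generate_small_areas(60, 3, seed = 3)
  cc <- aggregate_catchments(pop$areas,
                             assign_nearest_facility(pop$areas,
                                                     pop$facilities))
  mix <- area_quintile_mix(pop$households,
                           compute_quintiles(pop$households$income))
  d <- compute_demand(cc, default_condition_profiles(), quintile_mix = mix)
  # eligible quintiles are the poorer four, so multipliers exceed 1
  expect_true(all(d$by_condition$risk_multiplier > 1))
  # the quintile gradient itself conserves the population death total
  cp <- default_condition_profiles()
  rates <- adjust_mortality_by_quintile(cp$mortality_per_1000[4],
                                        cp$mortality_ratio[4])
  expect_equal(sum(0.2 * rates), cp$mortality_per_1000[4], tolerance = 1e-9)
})

test_that("zero condition contacts leaves household visits as the demand floor", {
  pop <- generate_small_areas(40, 2, seed = 6)
  cc <- aggregate_catchments(pop$areas,
                             assign_nearest_facility(pop$areas,
                                                     pop$facilities))
  cp <- default_condition_profiles()
  cp$contacts_per_affected_year <- 0
  p0 <- copc_params(social_support_contacts_per_capita = 0)
  d <- compute_demand(cc, cp, params = p0)
  expect_equal(d$total_cspc, sum(pop$areas$households))
})

test_that("Waterberg demand reproduces per-class visits per capita", {
  d <- waterberg_demand(waterberg_fixture())
  vpc <- setNames(d$by_class$visits_per_capita, d$by_class$class)
  expect_equal(unname(vpc["proximal"]), 2.96, tolerance = 0.01 / 2.96)
  expect_equal(unname(vpc["distal"]), 2.98, tolerance = 0.01 / 2.98)
  expect_equal(unname(vpc["remote"]), 2.95, tolerance = 0.01 / 2.95)
})

test_that("calibrated contact profile reproduces the condition consultation shares", {
  wb <- waterberg_fixture()
  cp <- default_condition_profiles()
  # modelled condition CSPC at the district scale, without risk uplift
  cspc <- wb$eligible_population * cp$prevalence_per_1000 / 1000 *
    cp$contacts_per_affected_year
  share <- 100 * cspc / sum(cspc)
  ref_share <- 100 * wb$conditions$consultations /
    sum(wb$conditions$consultations)
  expect_equal(round(share), round(ref_share))
  expect_true(all(abs(share - ref_share) < 1))
})
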