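test_that("single facility captures every area; empty facility set errors", {
  areas <- make_areas(lat = c(-24, -24.1, -24.2), lon = c(28, 28.1, 28.2),
                      population = c(100, 200, 300))
  fac <- make_facilities(-24.05, 28.05)
  a <- assign_nearest_facility(areas, fac)
  expect_true(all(a$facility_id == "F01"))
  expect_error(assign_nearest_facility(areas, fac[0, ]), "facility")
})

test_that("equidistant areas break ties toward the lowest facility id", {
  areas <- make_areas(lat = 0, lon = 0, population = 10)
  fac <- make_facilities(lat = c(0, 0), lon = c(0.1, -0.1))  # symmetric
  a <- assign_nearest_facility(areas, fac)
  expect_equal(a$facility_id, "F01")
  # same result when facility rows are given in reverse order
  a2 <- assign_nearest_facility(areas, fac[2:1, ])
  expect_equal(a2$facility_id, "F01")
})

test_that("assignment matches the brute-force pairwise oracle on random instances", {
  set.seed(99)
  for (rep in 1:3) {
    areas <- make_areas(lat = runif(50, -25, -23), lon = runif(50, 27, 29),
                        population = rep(10, 50))
    fac <- make_facilities(lat = runif(6, -25, -23), lon = runif(6, 27, 29))
    got <- assign_nearest_facility(areas, fac)$facility_id
    expect_equal(got, brute_force_nearest(areas, fac))
  }
})

test_that("density classification follows the 2 km / 200 p-km2 rules", {
  expect_equal(classify_density(1.5, 50), "proximal")
  expect_equal(classify_density(5, 300), "distal")
  expect_equal(classify_density(5, 100), "remote")
  # boundaries fall on the non-proximal / remote side
  expect_equal(classify_density(2.0, 1000), "distal")
  expect_equal(classify_density(5, 200), "remote")
  expect_error(classify_density(-1, 50), "distance")
  expect_error(classify_density(1, -5), "density")
})

test_that("catchment aggregation partitions areas and conserves totals", {
  set.seed(7)
  areas <- make_areas(lat = runif(40, -25, -23), lon = runif(40, 27, 29),
                      population = sample(50:500, 40),
                      households = sample(10:100, 40))
  areas$area_km2 <- areas$population / runif(40, 20, 1000)
  fac <- make_facilities(lat = runif(3, -25, -23), lon = runif(3, 27, 29))
  cc <- aggregate_catchments(areas, assign_nearest_facility(areas, fac))
  expect_equal(sum(cc$by_class$population), sum(areas$population))
  expect_equal(sum(cc$by_class$households), sum(areas$households))
  expect_equal(sum(cc$by_facility_class$population), sum(areas$population))
  expect_equal(sum(cc$by_class$n_areas), nrow(areas))
  # each area appears in exactly one class of one catchment
  expect_equal(sort(cc$area_class$area_id), sort(areas$area_id))
})

test_that("empty area set yields zero-total profiles", {
  areas <- make_areas(lat = numeric(0), lon = numeric(0),
                      population = numeric(0))
  cc <- aggregate_catchments(areas, data.frame())
  expect_equal(cc$by_class$population, rep(0, 3))
  expect_equal(cc$by_class$households, rep(0, 3))
})

test_that("unassigned areas trigger an integrity error", {
  areas <- make_areas(lat = c(0, 0.1), lon = c(0, 0.1),
                      population = c(10, 20))
  bad <- data.frame(area_id = "T001", facility_id = "F01",
                    distance_km = 1, stringsAsFactors = FALSE)
  expect_error(aggregate_catchments(areas, bad), "assigned")
})

test_that("the Waterberg layer reproduces its class populations exactly", {
  wb <- waterberg_fixture()
  cc <- aggregate_catchments(wb$areas,
                             assign_nearest_facility(wb$areas, wb$facilities))
  got <- setNames(cc$by_class$population, cc$by_class$class)
  expect_equal(unname(got[c("proximal", "distal", "remote")]),
               c(364919, 200887, 64759))
  hh <- setNames(cc$by_class$households, cc$by_class$class)
  expect_equal(unname(hh[c("proximal", "distal", "remote")]),
               c(96886, 50943, 20517))
})
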