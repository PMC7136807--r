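#' The Waterberg reference scenario
#'
#' A deterministic, directly assigned (not sampled) planning scenario for the
#' Waterberg district of Limpopo, South Africa: 630 565 people in 168 345
#' households eligible for community-based care, split across the three
#' service classes, with the seven-condition consultation and mortality
#' profile and the reference impact figures used throughout the package's
#' worked examples and tests.
#'
#' @details The returned object contains:
#' \describe{
#'   \item{areas, facilities}{a synthetic 12-area, 4-facility layer built so
#'     that nearest-facility assignment and density classification reproduce
#'     the class totals exactly: populations 364 919 / 200 887 / 64 759 and
#'     households 96 886 / 50 943 / 20 517 for proximal / distal / remote.}
#'   \item{class_workload}{per-class population, households and annual
#'     condition-specific person contacts (CSPC): 1 080 229 / 599 506 /
#'     190 748 (total 1 870 482).}
#'   \item{conditions}{the seven condition profiles augmented with the
#'     scenario's annual condition-specific consultations, baseline deaths
#'     (18, 237, 264, 1368, 146, 1831, 416), and its reference lives-saved,
#'     life-years-saved and cost-per-life-year figures. For HIV, TB and NCD
#'     the lives-saved figures reproduce from baseline deaths times expected
#'     effectiveness; the maternal, infant, child and acute figures embed
#'     additional counting conventions (e.g. stillbirths valued at age 0) and
#'     are carried as scenario constants.}
#'   \item{impact_reference}{district totals: lives saved 932 (490-1472),
#'     unadjusted life-years saved 36 134 (17 854-53 278), 35 877 after the
#'     all-cause cohort adjustment, and 4 279 deaths attributable to the
#'     covered conditions.}
#'   \item{unit_costs}{the 18-line unit-cost table of [default_unit_costs()].}
#'   \item{benefit_components}{the scenario's annual benefit decomposition
#'     for the headline benefit-to-cost ratio: R155m district savings
#'     (health-system plus HIV/TB treatment savings) and R175m societal
#'     benefits (poverty reduction and GDP growth).}
#'   \item{eligible_population}{630 565; the scenario is defined net of the
#'     privately insured top income quintile, so no further quintile
#'     exclusion applies.}
#' }
#'
#' @return a list of class `copc_scenario`.
#' @seealso [waterberg_demand()], [default_unit_costs()]
#' @export
#' @examples
#' wb <- waterberg_fixture()
#' sum(wb$class_workload$population)
waterberg_fixture <- function() {
  class_workload <- data.frame(
    class = c("proximal", "distal", "remote"),
    population = c(364919, 200887, 64759),
    households = c(96886, 50943, 20517),
    cspc = c(1080229, 599506, 190748),
    stringsAsFactors = FALSE
  )

  facilities <- data.frame(
    facility_id = sprintf("F%02d", 1:4),
    lat = c(-24.0, -24.0, -24.6, -24.6),
    lon = c(28.0, 28.6, 28.0, 28.6),
    stringsAsFactors = FALSE
  )

  # Four areas per class, one anchored at each facility; splits are exact.
  split4 <- function(total) allocate_integer(total, rep(0.25, 4))
  mk_class <- function(class, dist_km, density, pop_total, hh_total) {
    pops <- split4(pop_total)
    hhs <- split4(hh_total)
    dlat <- dist_km / 110.574
    data.frame(
      class = class,
      facility = facilities$facility_id,
      lat = facilities$lat + dlat,
      lon = facilities$lon,
      area_km2 = pops / density,
      households = hhs,
      population = pops,
      stringsAsFactors = FALSE
    )
  }
  raw <- rbind(
    mk_class("proximal", 1.0, 1500, 364919, 96886),
    mk_class("distal",   6.0,  350, 200887, 50943),
    mk_class("remote",  15.0,   60,  64759, 20517)
  )
  age_shares <- c(pop_0 = 0.025, pop_1_6 = 0.13, pop_7_14 = 0.16,
                  pop_15_39 = 0.38, pop_40_49 = 0.10, pop_50_59 = 0.09,
                  pop_60p = 0.105)
  bands <- t(vapply(raw$population, allocate_integer, numeric(7),
                    p = age_shares))
  colnames(bands) <- names(age_shares)
  areas <- data.frame(
    area_id = sprintf("WB%02d", seq_len(nrow(raw))),
    lat = raw$lat, lon = raw$lon, area_km2 = raw$area_km2,
    households = raw$households, bands, population = raw$population,
    median_income = NA_real_,
    stringsAsFactors = FALSE
  )

  profiles <- default_condition_profiles()
  conditions <- cbind(profiles, data.frame(
    consultations = c(159048, 114126, 113975, 180453, 153268, 177720, 52967),
    baseline_deaths = c(18, 237, 264, 1368, 146, 1831, 416),
    lives_saved = c(7, 48, 85, 506, 54, 220, 12),
    life_years_saved = c(3970, 2863, 5120, 14171, 1885, 7689, 437),
    cost_per_life_year = c(3039, 3282, 1833, 807, 5209, 1466, 8826)
  ))

  structure(list(
    areas = areas,
    facilities = facilities,
    class_workload = class_workload,
    conditions = conditions,
    impact_reference = list(
      lives = c(lower = 490, expected = 932, upper = 1472),
      life_years = c(lower = 17854, expected = 36134, upper = 53278),
      life_years_adjusted = 35877,
      attributable_mortality = 4279
    ),
    unit_costs = default_unit_costs(),
    benefit_components = c(district_savings = 155e6,
                           societal_benefits = 175e6),
    eligible_population = 630565,
    n_facility_links = 103
  ), class = "copc_scenario")
}

#' @export
print.copc_scenario <- function(x, ...) {
  cat("Waterberg reference scenario:",
      format(x$eligible_population, big.mark = " "),
      "eligible people,", sum(x$class_workload$households), "households,",
      format(sum(x$class_workload$cspc), big.mark = " "), "CSPC/year\n")
  invisible(x)
}

#' Demand profile of the Waterberg reference scenario
#'
#' Builds the [compute_demand()]-compatible demand object directly from the
#' scenario's encoded class workload and condition consultations (the
#' scenario is defined at the aggregate level; its total workload includes
#' comprehensive household care beyond the condition-specific profile).
#'
#' @param fixture the object returned by [waterberg_fixture()].
#' @return a `copc_demand` object (see [compute_demand()]).
#' @export
#' @examples
#' d <- waterberg_demand(waterberg_fixture())
#' d$by_class$visits_per_capita
waterberg_demand <- function(fixture = waterberg_fixture()) {
  cw <- fixture$class_workload
  by_class <- data.frame(
    class = cw$class,
    population = cw$population,
    households = cw$households,
    household_visits = cw$households,
    total_cspc = cw$cspc,
    visits_per_capita = cw$cspc / cw$population,
    stringsAsFactors = FALSE
  )
  by_condition <- data.frame(
    condition_id = fixture$conditions$condition_id,
    cspc = fixture$conditions$consultations,
    stringsAsFactors = FALSE
  )
  structure(list(
    by_class = by_class,
    by_condition = by_condition,
    total_cspc = sum(cw$cspc),
    condition_cspc = sum(by_condition$cspc),
    household_visits = sum(cw$households),
    eligible_population = fixture$eligible_population,
    n_facilities = nrow(fixture$facilities)
  ), class = "copc_demand")
}
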