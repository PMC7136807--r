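#' Cost per life-year saved
#'
#' Total annual programme cost divided by annual life-years saved, rounded to
#' the rand.
#'
#' @param total_cost ZAR/year (>= 0).
#' @param life_years life-years saved per year (> 0).
#' @return ZAR per life-year saved (whole rand).
#' @export
#' @examples
#' cost_per_life_year(96399102, 36134)
cost_per_life_year <- function(total_cost, life_years) {
  if (any(life_years <= 0)) stop_arg("life_years must be > 0")
  if (any(total_cost < 0)) stop_arg("total_cost must be >= 0")
  round_half_up(total_cost / life_years)
}

#' Threshold effectiveness at a cost-effectiveness benchmark
#'
#' The uniform effectiveness e at which the cost per life-year saved equals a
#' benchmark (e.g. GDP per capita): solving
#' `total_cost / (e * sum(deaths * life_years_per_life)) = benchmark` gives
#' the closed form `e = total_cost / (benchmark * sum(deaths * lyl))`.
#'
#' @param total_cost annual programme cost, ZAR.
#' @param baseline_deaths_by_condition annual baseline deaths per condition.
#' @param ly_per_life_by_condition life-years gained per life saved, per
#'   condition.
#' @param benchmark cost-per-life-year benchmark, ZAR (> 0).
#' @return the threshold effectiveness (fraction).
#' @export
#' @examples
#' wb <- waterberg_fixture()$conditions
#' threshold_effectiveness(96399102, wb$baseline_deaths,
#'                         wb$life_years_saved / wb$lives_saved, 99169)
threshold_effectiveness <- function(total_cost, baseline_deaths_by_condition,
                                    ly_per_life_by_condition, benchmark) {
  if (benchmark <= 0) stop_arg("benchmark must be > 0")
  denom <- sum(baseline_deaths_by_condition * ly_per_life_by_condition)
  if (denom <= 0) stop_arg("total potential life-years must be > 0")
  total_cost / (benchmark * denom)
}

#' Present value of a discounted earnings stream
#'
#' End-of-year annuity: `PV = sum_{t=1..years} income / (1 + rate)^t`. Used
#' under the human-capital approach to value the future earnings of lives
#' saved, with income first netted per perspective via [net_annual_income()].
#'
#' @param annual_net_income ZAR/year.
#' @param years whole years of earnings (>= 0).
#' @param rate annual discount rate (> -1); the planning default is the net
#'   growth-minus-inflation rate 0.0072.
#' @return present value, ZAR.
#' @export
#' @examples
#' discounted_earnings_pv(10000, 2, 0.10)
discounted_earnings_pv <- function(annual_net_income, years, rate) {
  if (years < 0) stop_arg("years must be >= 0")
  if (rate <= -1) stop_arg("rate must be > -1")
  if (years == 0) return(0)
  if (rate == 0) return(annual_net_income * years)
  annual_net_income * (1 - (1 + rate)^-years) / rate
}

#' Net annual income under a benefit perspective
#'
#' Adjusts gross household income for the benefit perspective:
#' `"poverty_reduction"` deducts tax (households keep net earnings; schooling
#' costs and child grants are not deducted because they flow to the
#' household), while `"gdp"` keeps tax (transferred to the state) but deducts
#' schooling costs and child grants as costs to the state. Both apply the
#' employment adjustment (`unemployment_adjustment` is the employed
#' fraction).
#'
#' @param gross_income ZAR/year; default `params$avg_household_income`.
#' @param perspective `"poverty_reduction"` or `"gdp"`.
#' @param params a [copc_params()] object.
#' @return net annual income, ZAR/year.
#' @export
net_annual_income <- function(gross_income = NULL,
                              perspective = c("poverty_reduction", "gdp"),
                              params = copc_params()) {
  perspective <- match.arg(perspective)
  gross_income <- gross_income %||% params$avg_household_income
  employed <- gross_income * params$unemployment_adjustment
  if (perspective == "poverty_reduction") {
    employed * (1 - params$tax_rate)
  } else {
    max(0, employed - params$schooling_cost - params$child_grant)
  }
}

#' HIV/TB care and treatment savings
#'
#' Savings from community-supported HIV and TB care: a saving multiplier
#' times the treated fraction times the annual treatment-and-medication cost
#' base, i.e. `2.2 x 0.203 x R88.3m = R39.4m` at the defaults.
#'
#' @param params a [copc_params()] object.
#' @return savings in ZAR millions per year.
#' @export
#' @examples
#' hivtb_treatment_savings()
hivtb_treatment_savings <- function(params = copc_params()) {
  params$hivtb_saving_multiplier * params$hivtb_treatment_fraction *
    params$hivtb_cost_base
}

#' Health-system savings from reduced utilisation
#'
#' Values reductions in clinic attendance, hospital admissions and outpatient
#' attendance at unit costs. The default unit costs are calibration values
#' (see vignette), not official tariffs.
#'
#' @param utilisation_deltas named vector with elements `clinic_visits`,
#'   `admissions`, `opd_visits` (annual reductions, >= 0).
#' @param unit_costs named vector with the same elements (ZAR each); default
#'   from `params`.
#' @param params a [copc_params()] object.
#' @return annual savings, ZAR.
#' @export
#' @examples
#' health_system_savings(c(clinic_visits = 110664, admissions = 4729,
#'                         opd_visits = 23646))
health_system_savings <- function(utilisation_deltas, unit_costs = NULL,
                                  params = copc_params()) {
  unit_costs <- unit_costs %||% c(clinic_visits = params$unit_cost_clinic_visit,
                                  admissions = params$unit_cost_admission,
                                  opd_visits = params$unit_cost_opd_visit)
  req <- c("clinic_visits", "admissions", "opd_visits")
  if (!all(req %in% names(utilisation_deltas)) ||
      !all(req %in% names(unit_costs))) {
    stop_arg("deltas and unit costs must name clinic_visits, admissions, opd_visits")
  }
  if (any(utilisation_deltas < 0) || any(unit_costs < 0)) {
    stop_arg("deltas and unit costs must be >= 0")
  }
  sum(utilisation_deltas[req] * unit_costs[req])
}

#' Annual wage injection into CHW households
#'
#' Sum of the CHW FTE, HBC FTE and team-leader staff lines of the cost
#' ledger, in ZAR millions to one decimal: the community-based wages paid
#' into (predominantly poor, often female-headed) local households.
#'
#' @param ledger a `copc_ledger`.
#' @param include character vector of staff categories to sum.
#' @return ZAR millions per year, one decimal.
#' @export
#' @examples
#' wages_injection(build_ledger())
wages_injection <- function(ledger,
                            include = c("CHW FTE", "HBC FTE", "TL")) {
  i <- match(include, ledger$items$category)
  if (any(is.na(i))) {
    stop_arg("ledger is missing staff line(s): ",
             paste(include[is.na(i)], collapse = ", "))
  }
  round_half_up(sum(ledger$items$total_rand[i]) / 1e6, 1)
}

#' Benefit-to-cost ratio
#'
#' Annual sum of all benefits divided by the total annual additional cost of
#' the service, to one decimal place.
#'
#' @param total_benefits ZAR/year (>= 0).
#' @param total_cost ZAR/year (> 0).
#' @return the BCR, one decimal.
#' @export
#' @examples
#' benefit_cost_ratio(330e6, 96399102)
benefit_cost_ratio <- function(total_benefits, total_cost) {
  if (total_cost <= 0) stop_arg("total_cost must be > 0")
  if (total_benefits < 0) stop_arg("total_benefits must be >= 0")
  round_half_up(total_benefits / total_cost, 1)
}

#' Benefit ledger: all annual benefit streams
#'
#' Assembles the component benefit streams of the community-based service:
#' health-system utilisation savings, HIV/TB treatment savings, the wage
#' injection into CHW households, and the discounted future earnings of the
#' lives saved (human-capital approach, per-condition horizons from life
#' expectancy minus `max(mean_age, working_age_start)`).
#'
#' @param ledger a `copc_ledger`.
#' @param impact a `copc_impact` (or a data frame with `lives_expected` and
#'   `mean_age` columns via `condition_profiles`).
#' @param condition_profiles condition-profile data frame (for mean ages).
#' @param utilisation_deltas see [health_system_savings()]; defaults to the
#'   district planning deltas (110 664 clinic visits, 4 729 admissions,
#'   23 646 OPD visits).
#' @param rate discount rate; default `params$net_growth_discount`.
#' @param perspective earnings perspective, see [net_annual_income()].
#' @param params a [copc_params()] object.
#' @return a list of class `copc_benefits` with each stream (ZAR/year), the
#'   lifetime earnings PV and its per-year annualisation, and `total`.
#' @export
benefit_ledger <- function(ledger, impact, condition_profiles,
                           utilisation_deltas = c(clinic_visits = 110664,
                                                  admissions = 4729,
                                                  opd_visits = 23646),
                           rate = NULL,
                           perspective = "poverty_reduction",
                           params = copc_params()) {
  rate <- rate %||% params$net_growth_discount
  hs <- health_system_savings(utilisation_deltas, params = params)
  hivtb <- hivtb_treatment_savings(params) * 1e6
  wages <- wages_injection(ledger) * 1e6
  net_income <- net_annual_income(perspective = perspective, params = params)
  bc <- impact$by_condition
  m <- match(bc$condition_id, condition_profiles$condition_id)
  horizon <- pmax(0, params$life_expectancy -
                    pmax(condition_profiles$mean_age[m],
                         params$working_age_start))
  pv <- sum(vapply(seq_len(nrow(bc)), function(i) {
    bc$lives_expected[i] *
      discounted_earnings_pv(net_income, horizon[i], rate)
  }, numeric(1)))
  earnings_annual <- if (sum(horizon * bc$lives_expected) > 0) {
    pv / stats::weighted.mean(horizon, bc$lives_expected)
  } else 0
  total <- hs + hivtb + wages + earnings_annual
  structure(list(
    health_system_savings = hs,
    hivtb_treatment_savings = hivtb,
    wages_injection = wages,
    household_earnings_pv = pv,
    household_earnings_annual = earnings_annual,
    discount_rate = rate,
    perspective = perspective,
    total = total
  ), class = "copc_benefits")
}

#' @export
print.copc_benefits <- function(x, ...) {
  cat(sprintf("Annual benefits (%s, discount %.4f): R%.1fm\n", x$perspective,
              x$discount_rate, x$total / 1e6))
  cat(sprintf("  health system R%.1fm; HIV/TB R%.1fm; wages R%.1fm; earnings R%.1fm/yr (PV R%.1fm)\n",
              x$health_system_savings / 1e6, x$hivtb_treatment_savings / 1e6,
              x$wages_injection / 1e6, x$household_earnings_annual / 1e6,
              x$household_earnings_pv / 1e6))
  invisible(x)
}

#' Economic summary: cost-effectiveness and cost-benefit headline figures
#'
#' @param ledger a `copc_ledger`.
#' @param life_years named or length-3 vector of annual life-years saved at
#'   `lower`, `expected`, `upper` effectiveness.
#' @param eligible_population people served.
#' @param baseline_deaths,ly_per_life per-condition inputs for threshold
#'   effectiveness.
#' @param benefits either a `copc_benefits` object or a numeric total
#'   (ZAR/year) for the BCR numerator.
#' @param params a [copc_params()] object.
#' @return a list of class `copc_economics`: per-capita cost, cost per
#'   life-year at the three bounds, threshold effectiveness at the GDP and
#'   household-income benchmarks, and the BCR.
#' @export
economic_summary <- function(ledger, life_years, eligible_population,
                             baseline_deaths, ly_per_life, benefits,
                             params = copc_params()) {
  lv <- if (!is.null(names(life_years))) {
    life_years[c("lower", "expected", "upper")]
  } else stats::setNames(life_years, c("lower", "expected", "upper"))
  total_benefits <- if (inherits(benefits, "copc_benefits")) {
    benefits$total
  } else benefits
  structure(list(
    per_capita_cost = round_half_up(
      ledger$overall_total / eligible_population, 2),
    cost_per_life_year = c(
      lower_effectiveness = cost_per_life_year(ledger$overall_total,
                                               lv[["lower"]]),
      expected = cost_per_life_year(ledger$overall_total, lv[["expected"]]),
      upper_effectiveness = cost_per_life_year(ledger$overall_total,
                                               lv[["upper"]])),
    threshold_effectiveness = c(
      gdp_per_capita = threshold_effectiveness(
        ledger$overall_total, baseline_deaths, ly_per_life,
        params$gdp_per_capita),
      avg_household_income = threshold_effectiveness(
        ledger$overall_total, baseline_deaths, ly_per_life,
        params$avg_household_income)),
    total_benefits = total_benefits,
    bcr = benefit_cost_ratio(total_benefits, ledger$overall_total)
  ), class = "copc_economics")
}

#' @export
print.copc_economics <- function(x, ...) {
  cat(sprintf("Per-capita cost R%.2f; cost/life-year R%d (R%d-R%d)\n",
              x$per_capita_cost, x$cost_per_life_year[["expected"]],
              x$cost_per_life_year[["upper_effectiveness"]],
              x$cost_per_life_year[["lower_effectiveness"]]))
  cat(sprintf("Threshold effectiveness: %.2f%% (GDP), %.2f%% (household income); BCR %.1f\n",
              100 * x$threshold_effectiveness[["gdp_per_capita"]],
              100 * x$threshold_effectiveness[["avg_household_income"]],
              x$bcr))
  invisible(x)
}
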