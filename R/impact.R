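#' Lives saved from baseline deaths and effectiveness
#'
#' Annual avertable deaths: baseline deaths times the effectiveness fraction,
#' rounded half-up to whole lives (matching tabulated planning figures, e.g.
#' 1368 x 0.37 = 506.16 -> 506).
#'
#' @param baseline_deaths annual deaths at baseline (>= 0).
#' @param effectiveness fraction of deaths averted, in \[0, 1\].
#' @return whole lives saved per year.
#' @export
#' @examples
#' lives_saved(1368, 0.37)
lives_saved <- function(baseline_deaths, effectiveness) {
  if (any(effectiveness < 0 | effectiveness > 1)) {
    stop_arg("effectiveness must lie in [0, 1]")
  }
  if (any(baseline_deaths < 0)) stop_arg("baseline_deaths must be >= 0")
  round_half_up(baseline_deaths * effectiveness)
}

#' Life-years saved per year
#'
#' Lives saved times the remaining expectancy of the affected group:
#' life expectancy minus the group's mean age. No utility or disability
#' adjustment is applied.
#'
#' @param lives lives saved per year (>= 0).
#' @param mean_age mean age of the affected group, years; must be below the
#'   life expectancy.
#' @param params a [copc_params()] object.
#' @return life-years saved per year.
#' @export
#' @examples
#' life_years_saved(506, 32)
life_years_saved <- function(lives, mean_age, params = copc_params()) {
  if (any(mean_age >= params$life_expectancy)) {
    stop_arg("mean_age must be below life expectancy (",
             params$life_expectancy, ")")
  }
  if (any(lives < 0)) stop_arg("lives must be >= 0")
  lives * (params$life_expectancy - mean_age)
}

#' Per-condition impact with lower/expected/upper bounds
#'
#' Applies each condition's effectiveness triplet to its baseline deaths,
#' rounding lives half-up at condition level before the life-year
#' multiplication, and totals across conditions.
#'
#' @param condition_profiles condition-profile data frame.
#' @param baseline_deaths named (by condition_id) or positionally matched
#'   vector of annual baseline deaths.
#' @param params a [copc_params()] object.
#' @return a list of class `copc_impact`: `by_condition` (baseline deaths,
#'   lives and life-years saved at each bound) and `totals` (summed bounds).
#' @export
#' @examples
#' wb <- waterberg_fixture()
#' impact_bounds(wb$conditions, wb$conditions$baseline_deaths)$by_condition
impact_bounds <- function(condition_profiles, baseline_deaths,
                          params = copc_params()) {
  if (!is.null(names(baseline_deaths))) {
    baseline_deaths <- baseline_deaths[condition_profiles$condition_id]
  }
  if (length(baseline_deaths) != nrow(condition_profiles) ||
      any(is.na(baseline_deaths))) {
    stop_arg("baseline_deaths must cover every condition profile")
  }
  lyl <- params$life_expectancy - condition_profiles$mean_age
  by_condition <- data.frame(
    condition_id = condition_profiles$condition_id,
    baseline_deaths = baseline_deaths,
    lives_lower = lives_saved(baseline_deaths, condition_profiles$eff_lower),
    lives_expected = lives_saved(baseline_deaths,
                                 condition_profiles$eff_expected),
    lives_upper = lives_saved(baseline_deaths, condition_profiles$eff_upper),
    stringsAsFactors = FALSE
  )
  by_condition$ly_lower <- by_condition$lives_lower * lyl
  by_condition$ly_expected <- by_condition$lives_expected * lyl
  by_condition$ly_upper <- by_condition$lives_upper * lyl
  totals <- colSums(by_condition[, -1])
  structure(list(by_condition = by_condition, totals = as.list(totals)),
            class = "copc_impact")
}

#' @export
print.copc_impact <- function(x, ...) {
  t <- x$totals
  cat(sprintf("Impact: %g lives saved/year (%g-%g); %g life-years (%g-%g)\n",
              t$lives_expected, t$lives_lower, t$lives_upper,
              t$ly_expected, t$ly_lower, t$ly_upper))
  invisible(x)
}

#' All-cause cohort mortality adjustment of life-years saved
#'
#' Deflates unadjusted life-years saved by a single calibrated factor to
#' allow for deaths from other causes in the saved cohort over the years
#' gained.
#'
#' @param total_life_years unadjusted life-years saved per year.
#' @param rate deflation fraction in \[0, 1); default
#'   `params$cohort_deflation_rate` (0.00711).
#' @param params a [copc_params()] object.
#' @return adjusted life-years, `total_life_years * (1 - rate)`.
#' @export
#' @examples
#' cohort_adjust(36134)
cohort_adjust <- function(total_life_years, rate = NULL,
                          params = copc_params()) {
  rate <- rate %||% params$cohort_deflation_rate
  if (rate < 0 || rate >= 1) stop_arg("rate must lie in [0, 1)")
  total_life_years * (1 - rate)
}

#' Write the per-condition impact table to CSV
#'
#' @param impact a `copc_impact` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_impact <- function(impact, path) {
  utils::write.csv(impact$by_condition, path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
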