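#' Model parameters for the COPC planning pipeline
#'
#' Constructs the single typed parameter object consumed by every downstream
#' stage. Defaults are the 2019 ZAR planning values for a rural South African
#' district: a full-time community health worker (CHW) works 180 days per year,
#' 7 hours per day, paid the 2019 minimum wage (R20/hour, R3500/month); a
#' condition-specific person contact (CSPC) takes 28 minutes in proximal and
#' distal areas and 30 minutes in remote areas; service classes split at 2 km
#' from the nearest facility and 200 persons/km2.
#'
#' @param ... named overrides of any default listed below.
#'
#' @details Monetary values are 2019 ZAR throughout; no inflation indexing is
#'   applied inside a run. Key defaults:
#' \describe{
#'   \item{life_expectancy}{60 years (national planning value).}
#'   \item{working_days_per_year, working_hours_per_day}{180 days, 7 h.}
#'   \item{minutes_per_cspc}{named vector, minutes per contact by service
#'     class: proximal 28, distal 28, remote 30.}
#'   \item{proximal_distance_km, remote_density_threshold}{2 km; 200 p/km2.}
#'   \item{chw_monthly_wage, hourly_wage}{R3500/month; R20/hour.}
#'   \item{tax_rate}{0.18 (standard rate).}
#'   \item{net_growth_discount}{0.0072/year (economic growth net of
#'     inflation); \code{sensitivity_discounts} 0.03 and 0.06.}
#'   \item{ict_saving_fraction}{0.15 saving of ICT over paper-based systems.}
#'   \item{gdp_per_capita, avg_household_income}{R99 169; R79 524.}
#'   \item{hivtb_saving_multiplier, hivtb_treatment_fraction,
#'     hivtb_cost_base}{2.2; 0.203; R88.3m — inputs to the HIV/TB
#'     treatment-savings formula.}
#'   \item{unit_cost_clinic_visit, unit_cost_opd_visit,
#'     unit_cost_admission}{R467.61, R962.17, R9621.65 — calibrated
#'     health-system unit costs (see vignette), not official tariffs.}
#'   \item{cspc_per_visit}{1.1115 — average CSPC delivered per household
#'     visit, calibrated on the Waterberg proximal class.}
#'   \item{max_households_per_remote_chw}{50 — caps the households a
#'     part-time remote CHW serves.}
#'   \item{chws_per_team, hbc_per_chw}{6.7 CHWs per team-leader team;
#'     0.186 home-based carers per CHW.}
#'   \item{social_support_contacts_per_capita}{1.19/year — comprehensive-care
#'     contacts (health promotion, adherence, palliative support) beyond the
#'     condition profile and the annual household visit.}
#'   \item{cohort_deflation_rate}{0.00711 — one-off deflation of life-years
#'     saved for all-cause mortality in the saved cohort.}
#'   \item{quintile_gradient}{"linear" or "geometric" mortality gradient
#'     across income quintiles.}
#'   \item{allocation_base}{"total" or "condition_specific" consultation base
#'     for allocating cost to conditions.}
#' }
#'
#' @return an object of class \code{copc_params} (a validated named list).
#' @seealso [load_params()], [default_condition_profiles()]
#' @export
#' @examples
#' p <- copc_params()
#' p$chw_monthly_wage
#' copc_params(life_expectancy = 65)$life_expectancy
copc_params <- function(...) {
  defaults <- list(
    life_expectancy = 60,
    working_days_per_year = 180,
    working_hours_per_day = 7,
    minutes_per_cspc = c(proximal = 28, distal = 28, remote = 30),
    proximal_distance_km = 2,
    remote_density_threshold = 200,
    chw_monthly_wage = 3500,
    hourly_wage = 20,
    tax_rate = 0.18,
    net_growth_discount = 0.0072,
    sensitivity_discounts = c(0.03, 0.06),
    ict_saving_fraction = 0.15,
    gdp_per_capita = 99169,
    avg_household_income = 79524,
    hivtb_saving_multiplier = 2.2,
    hivtb_treatment_fraction = 0.203,
    hivtb_cost_base = 88.3,
    unit_cost_clinic_visit = 467.61,
    unit_cost_opd_visit = 962.17,
    unit_cost_admission = 9621.65,
    schooling_cost = 15000,
    child_grant = 5100,
    unemployment_adjustment = 0.393,
    cspc_per_visit = 1.1115,
    max_households_per_remote_chw = 50,
    chws_per_team = 6.7,
    hbc_per_chw = 0.186,
    household_visits_per_year = 1,
    social_support_contacts_per_capita = 1.19,
    cohort_deflation_rate = 0.00711,
    district_staffing = c(clinical_supervisor = 49, clinical_associate = 63,
                          family_physician = 6),
    district_staffing_reference_pop = 630565,
    ncd_weight_diabetes = 0.17,
    working_age_start = 15,
    quintile_gradient = "linear",
    allocation_base = "total"
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1]]) &&
      is.null(names(overrides))) {
    overrides <- overrides[[1]]
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop_arg("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  p <- utils::modifyList(defaults, overrides)
  validate_params(p)
  structure(p, class = "copc_params")
}

validate_params <- function(p) {
  fracs <- c("tax_rate", "ict_saving_fraction", "hivtb_treatment_fraction",
             "unemployment_adjustment", "cohort_deflation_rate",
             "ncd_weight_diabetes")
  for (f in fracs) {
    v <- p[[f]]
    if (!is.numeric(v) || any(v < 0) || any(v > 1)) {
      stop_arg("parameter '", f, "' must be a fraction in [0, 1], got ", v)
    }
  }
  money <- c("chw_monthly_wage", "hourly_wage", "gdp_per_capita",
             "avg_household_income", "unit_cost_clinic_visit",
             "unit_cost_opd_visit", "unit_cost_admission", "schooling_cost",
             "child_grant", "hivtb_cost_base")
  for (f in money) {
    if (!is.numeric(p[[f]]) || any(p[[f]] < 0)) {
      stop_arg("parameter '", f, "' must be a non-negative amount")
    }
  }
  if (p$proximal_distance_km <= 0) {
    stop_arg("parameter 'proximal_distance_km' must be > 0")
  }
  if (p$remote_density_threshold <= 0) {
    stop_arg("parameter 'remote_density_threshold' must be > 0")
  }
  if (p$life_expectancy <= 0) stop_arg("'life_expectancy' must be > 0")
  if (any(p$minutes_per_cspc <= 0)) {
    stop_arg("'minutes_per_cspc' entries must be > 0")
  }
  if (!all(c("proximal", "distal", "remote") %in% names(p$minutes_per_cspc))) {
    stop_arg("'minutes_per_cspc' must name proximal, distal and remote")
  }
  if (!p$quintile_gradient %in% c("linear", "geometric")) {
    stop_arg("'quintile_gradient' must be 'linear' or 'geometric'")
  }
  if (!p$allocation_base %in% c("total", "condition_specific")) {
    stop_arg("'allocation_base' must be 'total' or 'condition_specific'")
  }
  invisible(p)
}

#' @export
print.copc_params <- function(x, ...) {
  cat("COPC planning parameters (2019 ZAR)\n")
  cat(sprintf("  CHW wage: R%d/month; %d days x %g h/year\n",
              x$chw_monthly_wage, x$working_days_per_year,
              x$working_hours_per_day))
  cat(sprintf("  CSPC minutes: proximal %g, distal %g, remote %g\n",
              x$minutes_per_cspc[["proximal"]], x$minutes_per_cspc[["distal"]],
              x$minutes_per_cspc[["remote"]]))
  cat(sprintf("  Classes: <%g km proximal; density threshold %g p/km2\n",
              x$proximal_distance_km, x$remote_density_threshold))
  cat(sprintf("  Life expectancy %g y; tax %g; discount %g (+%s)\n",
              x$life_expectancy, x$tax_rate, x$net_growth_discount,
              paste(x$sensitivity_discounts, collapse = ", ")))
  invisible(x)
}

#' Load model parameters (and optional condition overrides) from YAML
#'
#' Reads a config with optional top-level sections `params:` and
#' `conditions:`. Missing fields fall back to the defaults of
#' [copc_params()]; condition entries override matching fields of
#' [default_condition_profiles()] by `condition_id`.
#'
#' @param config_path path to a YAML file, or `NULL` for all defaults.
#' @return a list with elements `params` (class `copc_params`) and
#'   `conditions` (the condition-profile data frame).
#' @export
load_params <- function(config_path = NULL) {
  if (is.null(config_path)) {
    p <- copc_params()
    return(list(params = p, conditions = default_condition_profiles(p)))
  }
  if (!file.exists(config_path)) {
    stop_arg("config file not found: ", config_path)
  }
  cfg <- yaml::read_yaml(config_path)
  if (!is.list(cfg)) cfg <- list()
  overrides <- cfg$params %||% list()
  # tolerate scalar lists from YAML for vector-valued params
  for (nm in c("minutes_per_cspc", "sensitivity_discounts",
               "district_staffing")) {
    if (!is.null(overrides[[nm]])) overrides[[nm]] <- unlist(overrides[[nm]])
  }
  p <- do.call(copc_params, overrides)
  conditions <- default_condition_profiles(p)
  for (entry in cfg$conditions %||% list()) {
    id <- entry$condition_id
    if (is.null(id) || !id %in% conditions$condition_id) {
      stop_arg("conditions: entry with unknown or missing condition_id")
    }
    i <- match(id, conditions$condition_id)
    for (f in setdiff(names(entry), "condition_id")) {
      if (!f %in% names(conditions)) {
        stop_arg("conditions: unknown field '", f, "' for ", id)
      }
      conditions[[f]][i] <- entry[[f]]
    }
  }
  validate_condition_profiles(conditions, p)
  list(params = p, conditions = conditions)
}

#' Write parameters to YAML
#'
#' Serialises a `copc_params` object (and optionally condition profiles) so
#' that [load_params()] on the result reproduces the same object.
#'
#' @param params a `copc_params` object.
#' @param path output YAML path.
#' @param conditions optional condition-profile data frame to embed.
#' @return `path`, invisibly.
#' @export
save_params <- function(params, path, conditions = NULL) {
  stopifnot(inherits(params, "copc_params"))
  out <- list(params = lapply(unclass(params), function(v) {
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v
  }))
  if (!is.null(conditions)) {
    out$conditions <- lapply(seq_len(nrow(conditions)), function(i) {
      as.list(conditions[i, , drop = FALSE])
    })
  }
  yaml::write_yaml(out, path)
  invisible(path)
}
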