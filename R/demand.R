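#' Income quintiles of a household income distribution
#'
#' Computes the four quintile thresholds (20/40/60/80th percentiles, type-7
#' quantiles) and assigns every household to a quintile. A household whose
#' income equals a threshold falls in the lower quintile, so a degenerate
#' all-equal distribution places every household in Q1.
#'
#' @param household_incomes numeric vector of household incomes (ZAR/year),
#'   length >= 5.
#' @return a list of class `copc_quintiles`: `thresholds` (length 4),
#'   `quintile` (integer 1..5 per household) and `counts` (households per
#'   quintile).
#' @export
#' @examples
#' q <- compute_quintiles(1:100)
#' q$thresholds
compute_quintiles <- function(household_incomes) {
  if (length(household_incomes) < 5) {
    stop_arg("at least 5 households are required to form quintiles")
  }
  thresholds <- stats::quantile(household_incomes, c(0.2, 0.4, 0.6, 0.8),
                                names = FALSE, type = 7)
  quintile <- 1L + rowSums(outer(household_incomes, thresholds, `>`))
  structure(list(
    thresholds = thresholds,
    quintile = as.integer(quintile),
    counts = tabulate(quintile, nbins = 5)
  ), class = "copc_quintiles")
}

#' Per-area quintile mix
#'
#' Tabulates, per small area, how many of its households fall in each income
#' quintile.
#'
#' @param households data frame with `area_id` and `income` (one row per
#'   household), as produced by [generate_small_areas()].
#' @param quintiles a [compute_quintiles()] result computed over the same
#'   (or a national) income vector.
#' @return data frame `area_id`, `hh_q1`..`hh_q5`.
#' @export
area_quintile_mix <- function(households, quintiles) {
  q <- 1L + rowSums(outer(households$income, quintiles$thresholds, `>`))
  tab <- table(factor(households$area_id), factor(q, levels = 1:5))
  out <- data.frame(area_id = rownames(tab),
                    as.data.frame.matrix(tab),
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out) <- c("area_id", paste0("hh_q", 1:5))
  out
}

#' Population eligible for community-based care
#'
#' The top income quintile (Q5) is assumed privately insured and excluded
#' from service demand; eligibility is the population living in Q1-Q4
#' households. Each area's population is scaled by its non-Q5 household
#' share.
#'
#' @param areas areas data frame (with `population`, `households`).
#' @param quintile_mix output of [area_quintile_mix()], or `NULL` when the
#'   scenario is already defined net of Q5 (everyone eligible).
#' @return total eligible population (numeric scalar).
#' @export
eligible_population <- function(areas, quintile_mix = NULL) {
  if (is.null(quintile_mix)) return(sum(areas$population))
  m <- match(areas$area_id, quintile_mix$area_id)
  hh_tot <- rowSums(quintile_mix[m, paste0("hh_q", 1:5)])
  frac <- ifelse(hh_tot > 0,
                 1 - quintile_mix$hh_q5[m] / hh_tot, 1)
  sum(areas$population * frac)
}

#' Risk-adjust a mortality rate across income quintiles
#'
#' Spreads a base mortality rate over quintiles Q1 (poorest) to Q5 (richest)
#' so that rate(Q1)/rate(Q5) equals the condition's poorest:richest mortality
#' ratio while the quintile-weighted mean stays exactly the base rate.
#' The gradient is linear by default (`gradient = "geometric"` uses constant
#' rate ratios between adjacent quintiles instead); both are mean-preserving
#' by construction.
#'
#' @param base_rate base rate, deaths per 1000 per year (>= 0).
#' @param ratio poorest:richest mortality ratio (>= 1).
#' @param quintile_weights weights of the five quintiles in the population
#'   the base rate describes; must sum to 1. Default equal.
#' @param gradient `"linear"` or `"geometric"`.
#' @return numeric length-5 vector of per-quintile rates (Q1..Q5).
#' @export
#' @examples
#' adjust_mortality_by_quintile(10, 9.1)
adjust_mortality_by_quintile <- function(base_rate, ratio,
                                         quintile_weights = rep(0.2, 5),
                                         gradient = c("linear", "geometric")) {
  if (ratio < 1) stop_arg("mortality ratio must be >= 1")
  if (base_rate < 0) stop_arg("base_rate must be >= 0")
  if (length(quintile_weights) != 5 ||
      abs(sum(quintile_weights) - 1) > 1e-8) {
    stop_arg("quintile_weights must be 5 weights summing to 1")
  }
  gradient <- match.arg(gradient)
  shape <- switch(gradient,
    linear = 1 - (0:4) / 4 * (1 - 1 / ratio),
    geometric = ratio^(-(0:4) / 4)
  )
  rates <- base_rate * shape / sum(quintile_weights * shape)
  names(rates) <- paste0("Q", 1:5)
  rates
}

#' Compute risk-adjusted service demand
#'
#' Converts catchment populations into annual contact workload. Per
#' condition, the affected population (prevalence x eligible population) is
#' multiplied by the best-practice contacts per affected person per year and
#' by a quintile risk multiplier: the mean of the condition's quintile
#' mortality gradient over the eligible quintiles Q1-Q4 (the gradient is
#' mean-preserving over all five quintiles, so serving only the poorer four
#' raises demand). On top of condition-specific contacts, every eligible
#' household receives one annual visit, and a comprehensive-care component
#' (`params$social_support_contacts_per_capita`) covers health promotion,
#' adherence, rehabilitation and palliative support contacts.
#'
#' @param catchments a [aggregate_catchments()] result.
#' @param condition_profiles a condition-profile data frame
#'   ([default_condition_profiles()]).
#' @param params a [copc_params()] object.
#' @param quintile_mix optional [area_quintile_mix()] output; when supplied,
#'   Q5 households are excluded from eligibility and the eligible quintile
#'   weights come from the observed mix. When `NULL`, everyone is eligible
#'   with equal quintile weights over Q1-Q4.
#' @return a list of class `copc_demand`: `by_class` (population, households,
#'   household_visits, total_cspc, visits_per_capita per service class),
#'   `by_condition` (district condition CSPC), and scalar totals.
#' @export
compute_demand <- function(catchments, condition_profiles,
                           params = copc_params(), quintile_mix = NULL) {
  req <- c("condition_id", "contacts_per_affected_year",
           "prevalence_per_1000", "mortality_ratio")
  if (!all(req %in% names(condition_profiles))) {
    stop_arg("condition profiles are missing required fields")
  }
  bc <- catchments$by_class
  ac <- catchments$area_class

  if (!is.null(quintile_mix)) {
    m <- match(ac$area_id, quintile_mix$area_id)
    qm <- as.matrix(quintile_mix[m, paste0("hh_q", 1:5)])
    hh_tot <- rowSums(qm)
    elig_frac_area <- ifelse(hh_tot > 0, 1 - qm[, 5] / hh_tot, 1)
    elig_pop_area <- ac$population * elig_frac_area
    elig_hh_area <- ac$households * elig_frac_area
    q_weights <- colSums(qm) / sum(qm)       # national mix incl. Q5
    elig_weights <- c(colSums(qm)[1:4] / sum(qm[, 1:4]), 0)
  } else {
    elig_pop_area <- ac$population
    elig_hh_area <- ac$households
    q_weights <- rep(0.2, 5)
    elig_weights <- c(rep(0.25, 4), 0)
  }
  cls <- factor(ac$class, levels = c("proximal", "distal", "remote"))
  elig_pop <- as.numeric(tapply(elig_pop_area, cls, sum, default = 0))
  elig_hh <- as.numeric(tapply(elig_hh_area, cls, sum, default = 0))
  total_elig <- sum(elig_pop)
  if (total_elig <= 0) stop_arg("eligible population must be > 0")

  # district-level condition CSPC with quintile risk multiplier
  risk_mult <- vapply(seq_len(nrow(condition_profiles)), function(i) {
    grad <- adjust_mortality_by_quintile(
      1, condition_profiles$mortality_ratio[i], q_weights,
      gradient = params$quintile_gradient)
    sum(elig_weights * grad)
  }, numeric(1))
  cond_cspc <- total_elig * condition_profiles$prevalence_per_1000 / 1000 *
    condition_profiles$contacts_per_affected_year * risk_mult
  by_condition <- data.frame(
    condition_id = condition_profiles$condition_id,
    cspc = cond_cspc, risk_multiplier = risk_mult,
    stringsAsFactors = FALSE)

  # split condition + comprehensive-care workload across classes by
  # eligible population; household visits follow households
  hh_visits <- elig_hh * params$household_visits_per_year
  social <- elig_pop * params$social_support_contacts_per_capita
  cond_by_class <- sum(cond_cspc) * (elig_pop / total_elig)
  total_by_class <- cond_by_class + hh_visits + social
  by_class <- data.frame(
    class = levels(cls),
    population = elig_pop,
    households = elig_hh,
    household_visits = hh_visits,
    condition_cspc = cond_by_class,
    social_cspc = social,
    total_cspc = total_by_class,
    visits_per_capita = ifelse(elig_pop > 0, total_by_class / elig_pop, 0),
    stringsAsFactors = FALSE
  )
  structure(list(
    by_class = by_class,
    by_condition = by_condition,
    total_cspc = sum(total_by_class),
    condition_cspc = sum(cond_cspc),
    household_visits = sum(hh_visits),
    eligible_population = total_elig,
    n_facilities = length(unique(ac$facility_id))
  ), class = "copc_demand")
}

#' @export
print.copc_demand <- function(x, ...) {
  cat(sprintf("Service demand: %s CSPC/year over %s eligible people (%.2f per capita)\n",
              format(round(x$total_cspc), big.mark = " "),
              format(round(x$eligible_population), big.mark = " "),
              x$total_cspc / x$eligible_population))
  invisible(x)
}

#' Write demand tables to CSV
#'
#' @param demand a `copc_demand` object.
#' @param dir output directory; writes `demand.csv` (per-condition CSPC) and
#'   `demand_summary.csv` (per-class workload).
#' @return `dir`, invisibly.
#' @export
write_demand <- function(demand, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(demand$by_condition, file.path(dir, "demand.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(demand$by_class, file.path(dir, "demand_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
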