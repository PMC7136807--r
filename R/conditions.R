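#' Default condition profiles for the seven COPC service conditions
#'
#' One row per condition covered by community health worker teams:
#' maternal/neonatal health, infant health, child health, HIV care and
#' treatment, TB care and treatment, non-communicable disease (NCD) care and
#' acute care. Each profile carries the contact workload, baseline mortality,
#' mean age of the affected group, the lower/expected/upper effectiveness
#' bounds on lives saved, and the poorest:richest mortality ratio used for
#' income-quintile risk adjustment.
#'
#' @details Effectiveness bounds are the literature-based planning values for
#'   well-managed community-based care, e.g. HIV 18/37/55% and NCD 6/12/18%.
#'   Mortality ratios between the poorest and richest quintiles: 5.9 maternal,
#'   4.9 child deaths (applied to both infant and child health), 9.1 TB, 2.78
#'   communicable disease (applied to HIV and, as the nearest stated category,
#'   to acute care). The NCD ratio is a prevalence-weighted mean of diabetes
#'   (3.3) and cardiovascular disease (2.3), weight
#'   \code{params$ncd_weight_diabetes} on diabetes (default 0.17, from
#'   incidences 2.4 vs 12 per 1000).
#'
#'   `contacts_per_affected_year` is a best-practice contact profile by
#'   condition; the shipped defaults were calibrated once so that the
#'   condition shares of contact workload match the Waterberg reference
#'   scenario (see vignette) and are fixed constants, not refit at run time.
#'
#' @param params a [copc_params()] object (used for the NCD weighting).
#' @return a data frame with columns `condition_id`,
#'   `contacts_per_affected_year`, `prevalence_per_1000`,
#'   `mortality_per_1000`, `mean_age`, `eff_lower`, `eff_expected`,
#'   `eff_upper`, `mortality_ratio`.
#' @export
#' @examples
#' default_condition_profiles()[, c("condition_id", "eff_expected")]
default_condition_profiles <- function(params = copc_params()) {
  w <- params$ncd_weight_diabetes
  ncd_ratio <- w * 3.3 + (1 - w) * 2.3
  profiles <- data.frame(
    condition_id = c("maternal_neonatal", "infant", "child", "hiv", "tb",
                     "ncd", "acute"),
    contacts_per_affected_year = c(10.5, 8.2, 3.3, 2.8, 20.3, 2.0, 0.5),
    prevalence_per_1000 = c(24, 22, 55, 101.3, 12, 140, 180),
    mortality_per_1000 = c(0.0285, 0.3759, 0.4187, 2.1695, 0.2315,
                           2.9037, 0.6597),
    mean_age = c(25, 0, 3, 32, 32, 45, 32),
    eff_lower    = c(0.17, 0.09, 0.14, 0.18, 0.18, 0.06, 0.05),
    eff_expected = c(0.33, 0.18, 0.28, 0.37, 0.37, 0.12, 0.10),
    eff_upper    = c(0.50, 0.27, 0.42, 0.55, 0.57, 0.18, 0.15),
    mortality_ratio = c(5.9, 4.9, 4.9, 2.78, 9.1, ncd_ratio, 2.78),
    stringsAsFactors = FALSE
  )
  validate_condition_profiles(profiles, params)
  profiles
}

validate_condition_profiles <- function(profiles, params = copc_params()) {
  req <- c("condition_id", "contacts_per_affected_year", "mortality_per_1000",
           "mean_age", "eff_lower", "eff_expected", "eff_upper",
           "mortality_ratio")
  missing <- setdiff(req, names(profiles))
  if (length(missing)) {
    stop_arg("condition profiles missing field(s): ",
             paste(missing, collapse = ", "))
  }
  if (anyDuplicated(profiles$condition_id)) {
    stop_arg("duplicate condition_id in profiles")
  }
  with(profiles, {
    if (any(eff_lower < 0 | eff_upper > 1)) {
      stop_arg("effectiveness bounds must lie in [0, 1]")
    }
    if (any(eff_lower > eff_expected | eff_expected > eff_upper)) {
      stop_arg("effectiveness bounds must satisfy lower <= expected <= upper")
    }
    if (any(mortality_per_1000 < 0)) stop_arg("mortality rate must be >= 0")
    if (any(mortality_ratio < 1)) stop_arg("mortality_ratio must be >= 1")
    if (any(mean_age >= params$life_expectancy)) {
      stop_arg("mean_age must be below life expectancy (",
               params$life_expectancy, ")")
    }
  })
  invisible(profiles)
}

#' Write / read condition profiles as CSV
#'
#' The CSV schema is
#' `condition_id,contacts_per_affected_year,mortality_per_1000,mean_age,`
#' `eff_lower,eff_expected,eff_upper,mortality_ratio`. On read, a missing
#' `prevalence_per_1000` column is filled from the defaults by condition_id.
#'
#' @param profiles condition-profile data frame.
#' @param path CSV path.
#' @return `write_condition_profiles()` returns `path` invisibly;
#'   `read_condition_profiles()` returns the profiles data frame.
#' @export
write_condition_profiles <- function(profiles, path) {
  cols <- c("condition_id", "contacts_per_affected_year",
            "mortality_per_1000", "mean_age", "eff_lower", "eff_expected",
            "eff_upper", "mortality_ratio")
  utils::write.csv(profiles[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_condition_profiles
#' @param params a [copc_params()] object used to validate on read.
#' @export
read_condition_profiles <- function(path, params = copc_params()) {
  profiles <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"prevalence_per_1000" %in% names(profiles)) {
    defaults <- default_condition_profiles(params)
    profiles$prevalence_per_1000 <-
      defaults$prevalence_per_1000[match(profiles$condition_id,
                                         defaults$condition_id)]
  }
  validate_condition_profiles(profiles, params)
  profiles
}
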