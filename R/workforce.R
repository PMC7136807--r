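#' Annual CHW contact capacity
#'
#' Contacts a full-time community health worker can deliver per year:
#' working days x working hours x 60 / minutes per contact. With the default
#' 180 days and 7 hours this is 2700 contacts/year at 28 minutes and 2520 at
#' 30 minutes.
#'
#' @param minutes_per_cspc minutes per condition-specific person contact
#'   (> 0).
#' @param params a [copc_params()] object.
#' @return contacts per CHW per year (numeric).
#' @export
#' @examples
#' chw_annual_capacity(28)
chw_annual_capacity <- function(minutes_per_cspc, params = copc_params()) {
  if (any(minutes_per_cspc <= 0)) stop_arg("minutes_per_cspc must be > 0")
  params$working_days_per_year * params$working_hours_per_day * 60 /
    minutes_per_cspc
}

#' Size the community-based workforce from demand
#'
#' Converts per-class contact workload into CHW full-time equivalents and
#' headcounts, home-based carers (HBC), team leaders/teams and district
#' supervisory posts.
#'
#' @details Per class, FTE = CSPC / (annual contact capacity x
#'   `cspc_per_visit`), where `cspc_per_visit` (> 1) reflects several
#'   condition-specific contacts being delivered within one household visit.
#'   In proximal and distal classes the headcount is the FTE rounded up; in
#'   remote classes CHWs work part time across scattered settlements, so the
#'   headcount is driven by a cap on households served per remote CHW
#'   (`max_households_per_remote_chw`, default 50). Teams (one team leader
#'   each) are sized as FTE / `chws_per_team`; HBC headcount scales with CHW
#'   headcount; one coordinator per facility; clinical supervisors, clinical
#'   associates and family physicians scale linearly with eligible
#'   population from the district staffing ratios.
#'
#' @param demand a `copc_demand` object ([compute_demand()] or
#'   [waterberg_demand()]).
#' @param params a [copc_params()] object.
#' @return a list of class `copc_workforce`: `by_class` (fte, chw_headcount,
#'   hbc_headcount, teams, cspc_per_chw, households_per_chw, pop_per_chw) and
#'   `district` (team_leaders, coordinators, clinical_supervisors,
#'   clinical_associates, family_physicians) plus totals.
#' @export
#' @examples
#' size_workforce(waterberg_demand())$by_class
size_workforce <- function(demand, params = copc_params()) {
  bc <- demand$by_class
  minutes <- params$minutes_per_cspc[bc$class]
  capacity <- chw_annual_capacity(minutes, params)
  eff_capacity <- capacity * params$cspc_per_visit
  fte <- bc$total_cspc / eff_capacity

  headcount <- ceiling(fte)
  remote <- bc$class == "remote"
  headcount[remote] <- pmax(
    ceiling(bc$households[remote] / params$max_households_per_remote_chw),
    ceiling(fte[remote]))
  headcount[bc$total_cspc == 0] <- 0

  hbc <- round_half_up(headcount * params$hbc_per_chw)
  teams <- round_half_up(fte / params$chws_per_team)

  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  by_class <- data.frame(
    class = bc$class,
    total_cspc = bc$total_cspc,
    chw_fte = fte,
    chw_headcount = headcount,
    hbc_headcount = hbc,
    teams = teams,
    cspc_per_chw = round_half_up(safe_div(bc$total_cspc, headcount)),
    households_per_chw = round_half_up(safe_div(bc$households, headcount)),
    pop_per_chw = round_half_up(safe_div(bc$population, headcount)),
    stringsAsFactors = FALSE
  )
  scale <- demand$eligible_population / params$district_staffing_reference_pop
  ds <- round_half_up(params$district_staffing * scale)
  district <- list(
    team_leaders = sum(teams),
    coordinators = demand$n_facilities %||% 0,
    clinical_supervisors = unname(ds["clinical_supervisor"]),
    clinical_associates = unname(ds["clinical_associate"]),
    family_physicians = unname(ds["family_physician"])
  )
  structure(list(
    by_class = by_class,
    district = district,
    total_fte = sum(fte),
    total_chw = sum(headcount),
    total_hbc = sum(hbc),
    total_teams = sum(teams)
  ), class = "copc_workforce")
}

#' @export
print.copc_workforce <- function(x, ...) {
  cat(sprintf("Workforce plan: %.0f CHW (%.1f FTE), %d HBC, %d teams/TL\n",
              x$total_chw, x$total_fte, x$total_hbc, x$total_teams))
  print(x$by_class, row.names = FALSE)
  invisible(x)
}

#' Write the workforce plan to CSV
#'
#' @param plan a `copc_workforce` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_workforce <- function(plan, path) {
  utils::write.csv(plan$by_class, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
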