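#' Default unit-cost table for the community-based service
#'
#' The 18 annual expenditure categories of the Waterberg reference scenario:
#' staff (CHW, HBC, team leaders, facility link-to-care, clinical associates,
#' family physicians, planned patient transport, clinical supervision),
#' equipment annualised straight-line with maintenance and replacement
#' (computers, Wi-Fi/UPS, phones, mobile system, tablets), and materials
#' (CHW kit, uniforms, leaflets, consumables). Marginal facility space costs
#' are excluded. `units` and `total_rand` are the scenario's planning values;
#' `unit_cost` is their quotient.
#'
#' @return data frame `category`, `units`, `total_rand`, `unit_cost`.
#' @export
#' @examples
#' sum(default_unit_costs()$total_rand)
default_unit_costs <- function() {
  uc <- data.frame(
    category = c("CHW FTE", "HBC FTE", "TL", "Facility link to care (LtC)",
                 "Clinical associate", "Family physician", "TL-PPT",
                 "Clinical supervisor", "Computers and printers",
                 "Wi-fi, UPS", "Cell phone for CHWs", "Mobile system",
                 "Tablets for OTL", "CHW kit", "Uniform", "Leaflets",
                 "CHW - materials", "TL - materials"),
    units = c(643, 120, 103, 103, 63, 6, 49, 49, 63, 63, 1283, 1283, 103,
              1161, 1161, 1161, 1104, 122),
    total_rand = c(27015933, 5030067, 19551511, 5132400, 24139080, 2912328,
                   1871371, 650302, 556920, 255969, 1539840, 2309760, 123720,
                   1741500, 298841, 2043360, 1104000, 122200),
    stringsAsFactors = FALSE
  )
  uc$unit_cost <- uc$total_rand / uc$units
  uc
}

#' Build the annual line-item cost ledger
#'
#' Prices every expenditure category and sums to the programme total in exact
#' integer-cent arithmetic. When a workforce plan is supplied, the CHW, HBC
#' and team-leader staff lines are re-priced at the plan's FTE/headcounts
#' times the category's annual unit cost (CHW and HBC at the minimum wage,
#' `chw_monthly_wage` x 12, when no unit cost is given); otherwise the
#' table's own units and totals are used verbatim.
#'
#' @param unit_costs a unit-cost table (`category`, `units`, and `total_rand`
#'   and/or `unit_cost`); see [default_unit_costs()].
#' @param params a [copc_params()] object.
#' @param plan optional `copc_workforce` plan to price staff lines from.
#' @return a list of class `copc_ledger`: `items` (category, units,
#'   unit_cost, total_cents, total_rand, pct_of_total) and `overall_total`
#'   (ZAR) / `overall_total_cents`.
#' @export
#' @examples
#' build_ledger()$overall_total
build_ledger <- function(unit_costs = default_unit_costs(),
                         params = copc_params(), plan = NULL) {
  if (!all(c("category", "units") %in% names(unit_costs))) {
    stop_arg("unit_costs must have 'category' and 'units' columns")
  }
  uc <- unit_costs
  if (is.null(uc$unit_cost) && is.null(uc$total_rand)) {
    stop_arg("unit_costs must provide 'unit_cost' and/or 'total_rand'")
  }
  if (is.null(uc$total_rand)) uc$total_rand <- NA_real_
  if (is.null(uc$unit_cost)) uc$unit_cost <- NA_real_
  uc$unit_cost <- ifelse(is.na(uc$unit_cost) & !is.na(uc$total_rand),
                         uc$total_rand / uc$units, uc$unit_cost)
  missing_cost <- is.na(uc$unit_cost) & is.na(uc$total_rand)
  if (any(missing_cost)) {
    stop_arg("missing unit cost for category: ",
             paste(uc$category[missing_cost], collapse = ", "))
  }

  if (!is.null(plan)) {
    stopifnot(inherits(plan, "copc_workforce"))
    staff_units <- c("CHW FTE" = plan$total_fte,
                     "HBC FTE" = plan$total_hbc,
                     "TL" = plan$district$team_leaders)
    for (cat in names(staff_units)) {
      i <- match(cat, uc$category)
      if (is.na(i)) stop_arg("unit_costs is missing staff category: ", cat)
      uc$units[i] <- staff_units[[cat]]
      if (cat %in% c("CHW FTE", "HBC FTE") && is.na(uc$unit_cost[i])) {
        uc$unit_cost[i] <- params$chw_monthly_wage * 12
      }
      uc$total_rand[i] <- NA_real_   # force re-pricing from units
    }
  }

  total_cents <- ifelse(!is.na(uc$total_rand),
                        round_half_up(uc$total_rand * 100),
                        round_half_up(uc$units * uc$unit_cost * 100))
  overall_cents <- sum(total_cents)
  items <- data.frame(
    category = uc$category,
    units = uc$units,
    unit_cost = uc$unit_cost,
    total_cents = total_cents,
    total_rand = total_cents / 100,
    pct_of_total = if (overall_cents > 0)
      round_half_up(100 * total_cents / overall_cents) else 0,
    stringsAsFactors = FALSE
  )
  structure(list(items = items,
                 overall_total_cents = overall_cents,
                 overall_total = overall_cents / 100),
            class = "copc_ledger")
}

#' @export
print.copc_ledger <- function(x, ...) {
  cat("Annual cost ledger (ZAR):\n")
  print(x$items[, c("category", "units", "total_rand", "pct_of_total")],
        row.names = FALSE)
  cat(sprintf("Overall total: %s\n",
              format(x$overall_total, big.mark = " ", scientific = FALSE)))
  invisible(x)
}

#' Apply the ICT saving to a paper-based system cost
#'
#' ICT-enabled data capture removes data clerks, filing and storage and
#' streamlines supervision, yielding an overall fractional saving
#' (`ict_saving_fraction`, default 15%) on the equivalent paper-based cost.
#'
#' @param paper_based_cost annual cost of the paper-based system (>= 0).
#' @param params a [copc_params()] object.
#' @return the ICT-enabled cost, `cost * (1 - ict_saving_fraction)`.
#' @export
#' @examples
#' apply_ict_saving(100)
apply_ict_saving <- function(paper_based_cost, params = copc_params()) {
  if (any(paper_based_cost < 0)) stop_arg("cost must be >= 0")
  paper_based_cost * (1 - params$ict_saving_fraction)
}

#' Allocate the programme cost to conditions by visit share
#'
#' Each condition receives the share of the overall total equal to its share
#' of consultations. With `base = "total"` the denominator is all
#' consultations (condition-specific plus household visits and
#' comprehensive-care contacts), leaving the household-visit share
#' unallocated to any condition; with `base = "condition_specific"` the full
#' total is split across conditions.
#'
#' @param ledger a `copc_ledger`.
#' @param demand a `copc_demand`.
#' @param base allocation base; defaults to `params$allocation_base`.
#' @param params a [copc_params()] object.
#' @return named numeric vector of ZAR/year per condition.
#' @export
allocate_cost_by_condition <- function(ledger, demand,
                                       base = NULL,
                                       params = copc_params()) {
  base <- base %||% params$allocation_base
  cond <- demand$by_condition
  denom <- switch(base,
                  total = demand$total_cspc,
                  condition_specific = sum(cond$cspc),
                  stop_arg("base must be 'total' or 'condition_specific'"))
  if (denom <= 0) stop_arg("total consultations must be > 0")
  # allocate in cents with exact conservation of the allocatable share
  allocatable_cents <- round_half_up(ledger$overall_total_cents *
                                       sum(cond$cspc) / denom)
  cents <- allocate_integer(allocatable_cents, cond$cspc / sum(cond$cspc))
  stats::setNames(cents / 100, cond$condition_id)
}

#' Write the ledger to CSV
#'
#' @param ledger a `copc_ledger`.
#' @param path output CSV (category, units, unit_cost, total_rand,
#'   pct_of_total), with a final overall-total row.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  out <- ledger$items[, c("category", "units", "unit_cost", "total_rand",
                          "pct_of_total")]
  out <- rbind(out, data.frame(category = "Overall total", units = NA,
                               unit_cost = NA,
                               total_rand = ledger$overall_total,
                               pct_of_total = 100))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
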