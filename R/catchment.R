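#' Assign each small area to its nearest facility
#'
#' Nearest-neighbour catchment assignment: every area centroid is linked to
#' the facility with the smallest great-circle distance. Ties are broken by
#' the lexicographically lowest `facility_id`.
#'
#' @param areas data frame with `area_id`, `lat`, `lon`.
#' @param facilities data frame with `facility_id`, `lat`, `lon`.
#' @return data frame `area_id`, `facility_id`, `distance_km`.
#' @export
#' @examples
#' wb <- waterberg_fixture()
#' head(assign_nearest_facility(wb$areas, wb$facilities))
assign_nearest_facility <- function(areas, facilities) {
  if (is.null(facilities) || nrow(facilities) == 0) {
    stop_arg("at least one facility is required")
  }
  fac <- facilities[order(facilities$facility_id), , drop = FALSE]
  # n_areas x n_facilities distance matrix (km)
  d <- vapply(seq_len(nrow(fac)), function(j) {
    geosphere::distHaversine(cbind(areas$lon, areas$lat),
                             c(fac$lon[j], fac$lat[j])) / 1000
  }, numeric(nrow(areas)))
  d <- matrix(d, nrow = nrow(areas))
  best <- apply(d, 1, which.min)  # which.min takes the first (lowest id) tie
  data.frame(
    area_id = areas$area_id,
    facility_id = fac$facility_id[best],
    distance_km = d[cbind(seq_len(nrow(areas)), best)],
    stringsAsFactors = FALSE
  )
}

#' Classify areas into proximal / distal / remote service classes
#'
#' Proximal: within `proximal_distance_km` (default 2 km) of the nearest
#' facility. Beyond that, distal if population density exceeds
#' `remote_density_threshold` (default 200 persons/km2), otherwise remote.
#' Boundary values (exactly 2 km, exactly 200 p/km2) fall on the
#' non-proximal / remote side — the conservative choice for staffing, since
#' remote classes carry a lower caseload per CHW.
#'
#' @param distance_km distance(s) to the nearest facility, km (>= 0).
#' @param density population density(ies), persons per km2 (>= 0).
#' @param params a [copc_params()] object.
#' @return character vector in `c("proximal", "distal", "remote")`.
#' @export
#' @examples
#' classify_density(c(1.5, 5, 5), c(50, 300, 100))
classify_density <- function(distance_km, density, params = copc_params()) {
  if (any(distance_km < 0)) stop_arg("distance_km must be >= 0")
  if (any(density < 0)) stop_arg("density must be >= 0")
  ifelse(distance_km < params$proximal_distance_km, "proximal",
         ifelse(density > params$remote_density_threshold, "distal", "remote"))
}

#' Aggregate assigned areas into per-facility catchment profiles
#'
#' Sums population and households by facility and service class. Density is
#' an area-level property (area population / area km2); every area lands in
#' exactly one class of one catchment, so totals are conserved exactly.
#'
#' @param areas data frame with `area_id`, `area_km2`, `households`,
#'   `population` (and coordinates).
#' @param assignment output of [assign_nearest_facility()].
#' @param params a [copc_params()] object.
#' @return a list of class `copc_catchments`: `by_facility_class` (facility,
#'   class, population, households, n_areas), `by_class` (class totals) and
#'   `area_class` (per-area facility, distance and class).
#' @export
aggregate_catchments <- function(areas, assignment, params = copc_params()) {
  if (nrow(areas) == 0) {
    empty <- data.frame(class = c("proximal", "distal", "remote"),
                        population = 0, households = 0, n_areas = 0L,
                        stringsAsFactors = FALSE)
    return(structure(list(
      by_facility_class = empty[0, ], by_class = empty,
      area_class = data.frame()), class = "copc_catchments"))
  }
  if (!all(areas$area_id %in% assignment$area_id)) {
    stop_arg("every area must be assigned to a facility")
  }
  m <- match(areas$area_id, assignment$area_id)
  density <- areas$population / areas$area_km2
  area_class <- data.frame(
    area_id = areas$area_id,
    facility_id = assignment$facility_id[m],
    distance_km = assignment$distance_km[m],
    class = classify_density(assignment$distance_km[m], density, params),
    population = areas$population,
    households = areas$households,
    stringsAsFactors = FALSE
  )
  agg <- stats::aggregate(
    cbind(population, households) ~ facility_id + class, data = area_class,
    FUN = sum)
  agg$n_areas <- stats::aggregate(
    area_id ~ facility_id + class, data = area_class, FUN = length)$area_id
  cls <- factor(area_class$class, levels = c("proximal", "distal", "remote"))
  by_class <- data.frame(
    class = levels(cls),
    population = as.numeric(tapply(area_class$population, cls, sum,
                                   default = 0)),
    households = as.numeric(tapply(area_class$households, cls, sum,
                                   default = 0)),
    n_areas = as.integer(tapply(area_class$area_id, cls, length,
                                default = 0L)),
    stringsAsFactors = FALSE
  )
  structure(list(by_facility_class = agg, by_class = by_class,
                 area_class = area_class),
            class = "copc_catchments")
}

#' @export
print.copc_catchments <- function(x, ...) {
  cat("Catchment profile (by service class):\n")
  print(x$by_class, row.names = FALSE)
  invisible(x)
}

#' Write catchment profiles to CSV
#'
#' @param catchments a `copc_catchments` object.
#' @param path output CSV (facility_id, class, population, households,
#'   n_areas).
#' @return `path`, invisibly.
#' @export
write_catchments <- function(catchments, path) {
  utils::write.csv(catchments$by_facility_class, path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
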