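#' Generate a synthetic small-area population layer
#'
#' Emulates a census small-area layer (SAL): many small areas of roughly
#' 20-500 households each, right-skewed household incomes, an age structure
#' covering infants through older adults, and a spatial layout that mixes
#' areas within 2 km of a facility with more distant dense and sparse areas,
#' so that all three service classes (proximal/distal/remote) occur.
#'
#' @param n_areas number of small areas (>= 1).
#' @param n_facilities number of primary-care facilities (>= 1).
#' @param seed integer seed; output is deterministic for a fixed seed.
#' @param profile `"rural"` (mean household size drawn in 3.2-4.0, ~43% of
#'   households below the extreme-poverty line) or `"urban"` (2.6-2.9, ~30%).
#' @param poverty_line household income (ZAR/year) defining extreme poverty
#'   for the income calibration; default 30 000.
#'
#' @details Incomes are lognormal (sdlog 1) with the log-mean set so the
#'   profile's extreme-poverty share holds in expectation; each area carries a
#'   modest area-level income effect so poverty clusters spatially (remote
#'   areas poorer). Disjoint internal age bands are 0, 1-6, 7-14, 15-39,
#'   40-49, 50-59 and 60+; per-area counts are integer-allocated so they sum
#'   exactly to the area population. Distances are great-circle between
#'   centroids.
#'
#' @return a list of class `copc_population` with data frames
#'   `areas` (area_id, lat, lon, area_km2, households, pop_0, pop_1_6,
#'   pop_7_14, pop_15_39, pop_40_49, pop_50_59, pop_60p, population,
#'   median_income), `facilities` (facility_id, lat, lon) and
#'   `households` (area_id, income).
#' @export
#' @examples
#' pop <- generate_small_areas(50, 3, seed = 1)
#' nrow(pop$areas)
generate_small_areas <- function(n_areas, n_facilities, seed = 1,
                                 profile = c("rural", "urban"),
                                 poverty_line = 30000) {
  if (n_areas < 1) stop_arg("n_areas must be >= 1")
  if (n_facilities < 1) stop_arg("n_facilities must be >= 1")
  profile <- match.arg(profile)

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)

  # Waterberg-like extent: ~1 degree box around (-24.3, 28.3)
  fac <- data.frame(
    facility_id = sprintf("F%03d", seq_len(n_facilities)),
    lat = stats::runif(n_facilities, -24.8, -23.8),
    lon = stats::runif(n_facilities, 27.8, 28.8),
    stringsAsFactors = FALSE
  )

  hh_size_range <- if (profile == "rural") c(3.2, 4.0) else c(2.6, 2.9)
  poverty_share <- if (profile == "rural") 0.43 else 0.30
  sdlog <- 1
  meanlog_base <- log(poverty_line) - stats::qnorm(poverty_share) * sdlog

  anchor <- sample.int(n_facilities, n_areas, replace = TRUE)
  # ~45% of areas within 2 km of their anchor facility, rest out to 30 km
  near <- stats::runif(n_areas) < 0.45
  dist_km <- ifelse(near, stats::runif(n_areas, 0.1, 1.9),
                    stats::runif(n_areas, 2.2, 30))
  bearing <- stats::runif(n_areas, 0, 2 * pi)
  lat <- fac$lat[anchor] + (dist_km / 110.574) * cos(bearing)
  lon <- fac$lon[anchor] + (dist_km / (111.32 * cos(fac$lat[anchor] * pi / 180))) *
    sin(bearing)

  households <- pmax(20L, pmin(500L,
    as.integer(round(stats::rlnorm(n_areas, log(90), 0.7)))))
  hh_size <- stats::runif(n_areas, hh_size_range[1], hh_size_range[2])
  population <- pmax(households, as.integer(round(households * hh_size)))

  # densities: near areas dense; far areas split across the 200 p/km2 line
  dense_far <- stats::runif(n_areas) < 0.5
  density <- ifelse(near,
    stats::runif(n_areas, 250, 3000),
    ifelse(dense_far, stats::runif(n_areas, 220, 1500),
           stats::runif(n_areas, 10, 150)))
  area_km2 <- population / density

  age_shares <- c(pop_0 = 0.025, pop_1_6 = 0.13, pop_7_14 = 0.16,
                  pop_15_39 = 0.38, pop_40_49 = 0.10, pop_50_59 = 0.09,
                  pop_60p = 0.105)
  bands <- t(vapply(population, function(n) {
    jitter <- age_shares * exp(stats::rnorm(length(age_shares), 0, 0.08))
    allocate_integer(n, jitter)
  }, numeric(length(age_shares))))
  colnames(bands) <- names(age_shares)

  # poorer far from facilities
  area_income_effect <- -0.15 * (dist_km > 10) + stats::rnorm(n_areas, 0, 0.25)
  hh <- data.frame(
    area_id = rep(sprintf("A%05d", seq_len(n_areas)), households),
    income = stats::rlnorm(sum(households),
                           rep(meanlog_base + area_income_effect, households),
                           sdlog),
    stringsAsFactors = FALSE
  )

  areas <- data.frame(
    area_id = sprintf("A%05d", seq_len(n_areas)),
    lat = lat, lon = lon, area_km2 = area_km2,
    households = households,
    bands,
    population = population,
    stringsAsFactors = FALSE
  )
  areas$median_income <- as.numeric(
    tapply(hh$income, hh$area_id, stats::median)[areas$area_id])

  structure(list(areas = areas, facilities = fac, households = hh,
                 profile = profile, seed = seed),
            class = "copc_population")
}

#' @export
print.copc_population <- function(x, ...) {
  cat(sprintf("Synthetic %s population: %d areas, %d facilities, %d households, %d people\n",
              x$profile, nrow(x$areas), nrow(x$facilities),
              nrow(x$households), sum(x$areas$population)))
  invisible(x)
}

#' Write a population layer to CSV
#'
#' Writes `areas.csv` (area_id, lat, lon, area_km2, households, age-band
#' counts, median_income) and `facilities.csv` (facility_id, lat, lon) into
#' `dir`.
#'
#' @param pop a `copc_population` object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_population <- function(pop, dir) {
  stopifnot(inherits(pop, "copc_population"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cols <- c("area_id", "lat", "lon", "area_km2", "households", "pop_0",
            "pop_1_6", "pop_7_14", "pop_15_39", "pop_40_49", "pop_50_59",
            "pop_60p", "median_income")
  utils::write.csv(pop$areas[, cols], file.path(dir, "areas.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(pop$facilities, file.path(dir, "facilities.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Map disjoint internal age bands onto overlapping condition age ranges
#'
#' Condition eligibility uses overlapping ranges (e.g. adults 15-49,
#' reproductive 15-35, NCD 40-50); internally populations are kept in
#' disjoint bands so totals conserve. This view maps disjoint band counts
#' onto a requested range by proportional overlap of whole years.
#'
#' @param areas the `areas` data frame of a population layer.
#' @param from,to inclusive age range in years (`to = Inf` for open-ended).
#' @return numeric vector of estimated persons in the range, per area.
#' @export
ageband_view <- function(areas, from, to = Inf) {
  bands <- list(pop_0 = c(0, 0), pop_1_6 = c(1, 6), pop_7_14 = c(7, 14),
                pop_15_39 = c(15, 39), pop_40_49 = c(40, 49),
                pop_50_59 = c(50, 59), pop_60p = c(60, 84))
  out <- numeric(nrow(areas))
  for (b in names(bands)) {
    lo <- bands[[b]][1]; hi <- bands[[b]][2]
    overlap <- max(0, min(hi, to) - max(lo, from) + 1)
    if (overlap > 0) out <- out + areas[[b]] * overlap / (hi - lo + 1)
  }
  out
}
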