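# Shared helpers: tiny in-code fixtures for module tests.

# a minimal areas table with explicit coordinates and densities
make_areas <- function(lat, lon, population, households = pmax(1, round(population / 4)),
                       area_km2 = population / 100) {
  n <- length(lat)
  data.frame(
    area_id = sprintf("T%03d", seq_len(n)),
    lat = lat, lon = lon, area_km2 = area_km2,
    households = households, population = population,
    stringsAsFactors = FALSE
  )
}

make_facilities <- function(lat, lon) {
  data.frame(facility_id = sprintf("F%02d", seq_along(lat)),
             lat = lat, lon = lon, stringsAsFactors = FALSE)
}

# brute-force nearest-facility oracle: full pairwise haversine minimisation
brute_force_nearest <- function(areas, facilities) {
  vapply(seq_len(nrow(areas)), function(i) {
    d <- geosphere::distHaversine(
      c(areas$lon[i], areas$lat[i]),
      cbind(facilities$lon, facilities$lat))
    facilities$facility_id[order(d, facilities$facility_id)[1]]
  }, character(1))
}
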