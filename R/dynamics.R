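#' Range centroid of a binary map
#'
#' Unweighted arithmetic mean of the suitable cells' center longitudes and
#' latitudes (planar mean; adequate for regional extents well away from the
#' poles and the antimeridian).
#'
#' @param bin A [binary_map()].
#' @return One-row tibble: `species`, `scenario`, `longitude`, `latitude`,
#'   `n_cells`.
#' @export
range_centroid <- function(bin) {
  cells <- map_to_tibble(bin) |> dplyr::filter(.data$value == 1)
  if (nrow(cells) == 0)
    stop(sprintf("empty range for '%s' (%s): no suitable cells",
                 bin$species, bin$scenario), call. = FALSE)
  tibble::tibble(
    species = bin$species, scenario = bin$scenario,
    longitude = mean(cells$longitude), latitude = mean(cells$latitude),
    n_cells = nrow(cells)
  )
}

#' Great-circle (haversine) distance
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (vectorized).
#' @return Distance in km on a sphere of radius 6371.0088 km.
#' @export
geodesic_distance <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * earth_radius_km * asin(pmin(1, sqrt(a)))
}

#' Initial great-circle bearing and 8-wind compass label
#'
#' Standard initial bearing from point 1 to point 2, in degrees clockwise
#' from north, with the compass label from 45-degree sectors centered on N,
#' NE, E, SE, S, SW, W, NW.
#'
#' @inheritParams geodesic_distance
#' @return Tibble: `bearing` in `[0, 360)` and `direction`; both NA for
#'   coincident points.
#' @export
bearing_direction <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  same <- lon1 == lon2 & lat1 == lat2
  dlon <- (lon2 - lon1) * to_rad
  y <- sin(dlon) * cos(lat2 * to_rad)
  x <- cos(lat1 * to_rad) * sin(lat2 * to_rad) -
    sin(lat1 * to_rad) * cos(lat2 * to_rad) * cos(dlon)
  bearing <- (atan2(y, x) / to_rad) %% 360
  winds <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")
  direction <- winds[(floor((bearing + 22.5) / 45) %% 8) + 1]
  bearing[same] <- NA_real_
  direction[same] <- NA_character_
  tibble::tibble(bearing = bearing, direction = direction)
}

#' Centroid migration between scenarios
#'
#' @param centroids Tibble of centroids (as stacked [range_centroid()] rows)
#'   for one or more species across scenarios.
#' @param reference Scenario treated as the origin (default `"current"`).
#' @return Tibble: `species`, `scenario`, `distance_km`, `bearing`,
#'   `direction` for every non-reference scenario.
#' @export
centroid_migration <- function(centroids, reference = "current") {
  centroids <- tibble::as_tibble(centroids)
  ref <- dplyr::filter(centroids, .data$scenario == reference) |>
    dplyr::select("species", ref_lon = "longitude", ref_lat = "latitude")
  fut <- dplyr::filter(centroids, .data$scenario != reference) |>
    dplyr::inner_join(ref, by = "species")
  bd <- bearing_direction(fut$ref_lon, fut$ref_lat,
                          fut$longitude, fut$latitude)
  tibble::tibble(
    species = fut$species, scenario = fut$scenario,
    distance_km = geodesic_distance(fut$ref_lon, fut$ref_lat,
                                    fut$longitude, fut$latitude),
    bearing = bd$bearing, direction = bd$direction
  )
}

#' Per-cell richness change between two scenarios
#'
#' @param current,future `richness_map`s on one grid.
#' @return A `richness_change_map` (matrix of future minus current counts).
#' @export
richness_change <- function(current, future) {
  if (!grids_identical(current$grid, future$grid))
    stop("richness maps are not aligned", call. = FALSE)
  structure(list(grid = current$grid,
                 values = future$values - current$values,
                 scenario = paste(future$scenario, "-", current$scenario)),
            class = "richness_change_map")
}
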