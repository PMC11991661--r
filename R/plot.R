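map_plot <- function(map, fill_lab, discrete = FALSE) {
  df <- map_to_tibble(map)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$longitude, .data$latitude,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = fill_lab) +
    ggplot2::theme_minimal()
  if (discrete) p else p + ggplot2::scale_fill_viridis_c()
}

#' @exportS3Method ggplot2::autoplot
autoplot.suitability_map <- function(object, ...) {
  map_plot(object, "Suitability") +
    ggplot2::ggtitle(sprintf("%s (%s)", object$species, object$scenario))
}

#' @exportS3Method ggplot2::autoplot
autoplot.binary_map <- function(object, ...) {
  df <- map_to_tibble(object)
  df$value <- factor(df$value, c(0, 1), c("unsuitable", "suitable"))
  ggplot2::ggplot(df, ggplot2::aes(.data$longitude, .data$latitude,
                                   fill = .data$value)) +
    ggplot2::geom_raster() + ggplot2::coord_equal() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = NULL) +
    ggplot2::ggtitle(sprintf("%s (%s), threshold %.3f", object$species,
                             object$scenario, object$threshold_used)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.richness_map <- function(object, ...) {
  map_plot(object, "Species richness") +
    ggplot2::ggtitle(sprintf("Stacked richness (%s)", object$scenario))
}

#' @exportS3Method ggplot2::autoplot
autoplot.category_map <- function(object, ...) {
  df <- map_to_tibble(object)
  df$value <- factor(df$value, levels = object$levels)
  ggplot2::ggplot(df, ggplot2::aes(.data$longitude, .data$latitude,
                                   fill = .data$value)) +
    ggplot2::geom_raster() + ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_d(drop = FALSE) +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = "Category") +
    ggplot2::theme_minimal()
}

#' Plot centroid migration trajectories
#'
#' @param centroids Stacked [range_centroid()] rows across scenarios.
#' @param reference Reference scenario (trajectory origins).
#' @return A ggplot: one arrow per species per future scenario.
#' @export
plot_centroid_migration <- function(centroids, reference = "current") {
  ref <- dplyr::filter(centroids, .data$scenario == reference) |>
    dplyr::select("species", ref_lon = "longitude", ref_lat = "latitude")
  fut <- dplyr::filter(centroids, .data$scenario != reference) |>
    dplyr::inner_join(ref, by = "species")
  ggplot2::ggplot(fut) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$ref_lon, y = .data$ref_lat,
                   xend = .data$longitude, yend = .data$latitude,
                   color = .data$scenario),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
    ) +
    ggplot2::geom_point(ggplot2::aes(.data$ref_lon, .data$ref_lat)) +
    ggplot2::labs(x = "Longitude", y = "Latitude", color = "Scenario") +
    ggplot2::theme_minimal()
}
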