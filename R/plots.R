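#' Plot a raster grid as a suitability-style map
#'
#' @param object A `raster_grid` (suitability map, binary range, layer...).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.raster_grid <- function(object, ...) {
  df <- grid_centres(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = "value") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.binary_range <- function(object, ...) {
  df <- grid_centres(object)
  df$presence <- factor(ifelse(is.na(df$value), NA,
                               ifelse(df$value > 0, "presence", "absence")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$presence)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(absence = "grey85",
                                          presence = "#2c7fb8"),
                               na.value = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  fill = sprintf("range (thr %.2f)", object$threshold)) +
    ggplot2::theme_minimal()
}

#' Bar chart of standardized variable importance
#'
#' @param object An `importance_table` from [jackknife_importance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.importance_table <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$iv_std)
  df$predictor <- factor(df$predictor, levels = df$predictor)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iv_std, y = .data$predictor)) +
    ggplot2::geom_col(fill = "#41ab5d") +
    ggplot2::labs(x = "standardized importance (max-min)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot suitability classes
#'
#' @param map A suitability `raster_grid`.
#' @return A ggplot object with the four standard suitability classes.
#' @export
plot_suitability_classes <- function(map) {
  df <- classify_suitability(map)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(extremely_low = "#f7fcf5", low = "#c7e9c0",
                 medium = "#74c476", high = "#238b45"),
      na.value = "white", drop = FALSE) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = "suitability") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
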