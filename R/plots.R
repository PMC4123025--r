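#' Map of campaign sites coloured by concentration
#'
#' @param object A `campaign`.
#' @param outcome Sample-table column to colour by (after the coarse mass is
#'   derived this can be `"coarse"`; defaults to `"pm10"`).
#' @param ... Unused.
#' @return A ggplot, faceted by city and season.
#' @export
autoplot.campaign <- function(object, outcome = "pm10", ...) {
  df <- object$samples
  if (!outcome %in% names(df)) {
    df <- compute_coarse(df)
  }
  ggplot(df, aes(x = .data$x_m / 1000, y = .data$y_m / 1000, colour = .data[[outcome]])) +
    geom_point(size = 2) +
    facet_grid(season ~ city) +
    scale_colour_viridis_c() +
    coord_equal() +
    labs(x = "x (km)", y = "y (km)", colour = outcome) +
    theme_minimal()
}

#' Lattice-prediction map
#'
#' @param grid A grid-prediction tibble (`x_m`, `y_m`, and a prediction
#'   column).
#' @param value Prediction column name.
#' @return A ggplot raster-style map.
#' @export
plot_prediction_grid <- function(grid, value = "pred_lur") {
  ggplot(grid, aes(x = .data$x_m / 1000, y = .data$y_m / 1000, colour = .data[[value]])) +
    geom_point(shape = 15, size = 1) +
    scale_colour_viridis_c() +
    coord_equal() +
    facet_wrap(~city) +
    labs(x = "x (km)", y = "y (km)", colour = "prediction") +
    theme_minimal()
}
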