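#' Plot an environmental layer
#'
#' @param object An `env_layer`.
#' @param ... Unused.
#' @return A ggplot raster of the layer (nodata cells blank).
#' @method autoplot env_layer
#' @export
autoplot.env_layer <- function(object, ...) {
  df <- tidy.env_layer(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$longitude, .data$latitude,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85",
                                  name = object$units) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$variable_code,
                  x = "Longitude", y = "Latitude") +
    ggplot2::theme_minimal()
}

#' Plot a suitability map
#'
#' @param object A `suitability_map`.
#' @param ... Unused.
#' @return A ggplot raster of the scores; the most suitable areas carry the
#'   highest values, up to the attainable maximum `sum(weights)`.
#' @method autoplot suitability_map
#' @export
autoplot.suitability_map <- function(object, ...) {
  df <- tidy.suitability_map(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$longitude, .data$latitude,
                                   fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85", name = "score",
                                  limits = c(0, object$max_score)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Habitat suitability",
                  subtitle = paste("layers:", paste(object$recipes, collapse = ", ")),
                  x = "Longitude", y = "Latitude") +
    ggplot2::theme_minimal()
}

#' Plot realized-niche envelopes
#'
#' One panel per environmental variable; for each ecoregion of the chosen
#' species, the observed range (min–max) as a thin line, the interquartile
#' band (p25–p75) as a thick line and the mean as a point — the five-number
#' envelope read the way practitioners use it for site selection.
#'
#' @param object A `niche_summary` tibble.
#' @param species Optional species to restrict to (default: all, faceted).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot niche_summary
#' @export
autoplot.niche_summary <- function(object, species = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(species)) df <- df[df$species %in% species, , drop = FALSE]
  df$region <- paste0(df$eco_name, " (", df$eco_id, ")")
  ggplot2::ggplot(df, ggplot2::aes(y = .data$region)) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$min, xmax = .data$max),
                            linewidth = 0.4, colour = "grey55") +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$p25, xmax = .data$p75),
                            linewidth = 2, colour = "#2c7fb8") +
    ggplot2::geom_point(ggplot2::aes(x = .data$mean), size = 1.8) +
    ggplot2::facet_grid(.data$species ~ .data$variable_code, scales = "free_x") +
    ggplot2::labs(x = "Environmental value", y = NULL,
                  title = "Realized-niche envelopes by ecoregion") +
    ggplot2::theme_minimal()
}
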