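#' Tidy a suitability map into a cell table
#'
#' @param x A `suitability_map`.
#' @param ... Unused.
#' @return Tibble with one row per grid cell: `row`, `col`, `longitude`,
#'   `latitude` (cell centers), `score` (`NA` = nodata).
#' @method tidy suitability_map
#' @export
tidy.suitability_map <- function(x, ...) {
  out <- cell_centers(x$georef)
  out$score <- as.vector(t(x$scores))
  out
}

#' One-row summary of a suitability map
#'
#' @param x A `suitability_map`.
#' @param ... Unused.
#' @return Tibble: `n_cells`, `n_scored` (non-nodata), `max_score`
#'   (attainable), `max_score_observed`, `mean_score`, `fraction_at_max`.
#' @method glance suitability_map
#' @export
glance.suitability_map <- function(x, ...) {
  s <- x$scores[!is.na(x$scores)]
  tibble::tibble(
    n_cells = length(x$scores),
    n_scored = length(s),
    max_score = x$max_score,
    max_score_observed = if (length(s)) max(s) else NA_real_,
    mean_score = if (length(s)) mean(s) else NA_real_,
    fraction_at_max = if (length(s)) mean(s == x$max_score) else NA_real_
  )
}

#' Tidy an environmental layer into a cell table
#'
#' @param x An `env_layer`.
#' @param ... Unused.
#' @return Tibble: `row`, `col`, `longitude`, `latitude`, `value`.
#' @method tidy env_layer
#' @export
tidy.env_layer <- function(x, ...) {
  out <- cell_centers(x$georef)
  out$value <- as.vector(t(x$values))
  out
}

#' One-row summary of a niche-summary table
#'
#' @param x A `niche_summary` tibble.
#' @param ... Unused.
#' @return Tibble: `n_rows`, `n_species`, `n_ecoregions`, `n_variables`,
#'   `n_pairs` (species-ecoregion combinations).
#' @method glance niche_summary
#' @export
glance.niche_summary <- function(x, ...) {
  tibble::tibble(
    n_rows = nrow(x),
    n_species = dplyr::n_distinct(x$species),
    n_ecoregions = dplyr::n_distinct(x$eco_id),
    n_variables = dplyr::n_distinct(x$variable_code),
    n_pairs = nrow(dplyr::distinct(x, .data$species, .data$eco_id))
  )
}
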