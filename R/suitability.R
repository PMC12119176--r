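#' Band recipe for suitability reclassification
#'
#' A per-variable scoring rule: cells whose value lies in `[lo, hi]`
#' (inclusive both ends, so a degenerate `p25 == p75` band still contains its
#' single value) score the recipe's weight; optional exclusion bounds force a
#' zero outside `[exclusion_min, exclusion_max]` regardless of band.
#'
#' @param variable_code Layer code the recipe applies to.
#' @param lo,hi Band bounds, `lo <= hi`.
#' @param weight Non-negative weight.
#' @param exclusion_min,exclusion_max Optional hard limits (`NA` = absent);
#'   when both present they must bracket the band.
#' @return One-row `band_recipe` tibble.
#' @export
band_recipe <- function(variable_code, lo, hi, weight = 1,
                        exclusion_min = NA_real_, exclusion_max = NA_real_) {
  stopifnot(lo <= hi, weight >= 0)
  if (!is.na(exclusion_min) && !is.na(exclusion_max)) {
    stopifnot(exclusion_min <= lo, hi <= exclusion_max)
  }
  out <- tibble::tibble(variable_code = variable_code, lo = lo, hi = hi,
                        weight = weight,
                        exclusion_min = exclusion_min,
                        exclusion_max = exclusion_max)
  class(out) <- unique(c("band_recipe", class(out)))
  out
}

#' Derive band recipes from envelope rows
#'
#' Turns niche-summary rows into scoring recipes. Mode `"iqr"` takes the
#' interquartile band `[p25, p75]` as the desired range and sets the observed
#' `[min, max]` as exclusion bounds; mode `"range"` uses the observed minimum
#' and maximum as the signposts, with no exclusions.
#'
#' @param rows A `niche_summary` tibble (one or more rows).
#' @param mode `"iqr"` or `"range"`.
#' @param weight Weight(s), recycled across rows. Higher weights mark
#'   variables the user deems more important.
#' @return A `band_recipe` tibble, one row per input row.
#' @examples
#' row <- tibble::tibble(species = "sp", eco_id = 1L, eco_name = "A",
#'                       variable_code = "bo_sst_x", units = "°C",
#'                       n_obs = 20L, min = 5, p25 = 10, mean = 15, p75 = 20,
#'                       max = 30)
#' recipe_from_summary(row, mode = "iqr")
#' @export
recipe_from_summary <- function(rows, mode = c("iqr", "range"), weight = 1) {
  if (!is.character(mode) || !all(mode %in% c("iqr", "range"))) {
    stop("unknown band mode: ", paste(setdiff(mode, c("iqr", "range")),
                                      collapse = ", "), call. = FALSE)
  }
  mode <- match.arg(mode)
  weight <- rep_len(weight, nrow(rows))
  stopifnot(all(weight >= 0))
  out <- if (mode == "iqr") {
    tibble::tibble(variable_code = rows$variable_code,
                   lo = rows$p25, hi = rows$p75, weight = weight,
                   exclusion_min = rows$min, exclusion_max = rows$max)
  } else {
    tibble::tibble(variable_code = rows$variable_code,
                   lo = rows$min, hi = rows$max, weight = weight,
                   exclusion_min = NA_real_, exclusion_max = NA_real_)
  }
  class(out) <- unique(c("band_recipe", class(out)))
  out
}

#' Reclassify a layer against a band recipe
#'
#' Binary scoring: cell value in `[lo, hi]` maps to 1, anything else to 0;
#' values outside the exclusion bounds (when present) are forced to 0.
#' Graded scoring (`graded = TRUE`) keeps the bell-curve reading — values
#' nearer the optimum rank higher: 2 inside the band, 1 inside the exclusion
#' envelope, 0 outside (requires exclusion bounds). Nodata stays nodata.
#'
#' @param layer An [env_layer()].
#' @param recipe A one-row `band_recipe` with the same `variable_code`.
#' @param graded Use the three-level 2/1/0 scheme instead of binary 1/0.
#' @return An [env_layer()] of scores on the same grid.
#' @export
reclassify_band <- function(layer, recipe, graded = FALSE) {
  stopifnot(inherits(layer, "env_layer"), nrow(recipe) == 1)
  if (!identical(layer$variable_code, recipe$variable_code)) {
    stop("recipe is for `", recipe$variable_code, "` but layer is `",
         layer$variable_code, "`", call. = FALSE)
  }
  v <- layer$values
  in_band <- v >= recipe$lo & v <= recipe$hi
  if (graded) {
    if (is.na(recipe$exclusion_min) || is.na(recipe$exclusion_max)) {
      stop("graded scoring needs exclusion bounds in the recipe", call. = FALSE)
    }
    in_env <- v >= recipe$exclusion_min & v <= recipe$exclusion_max
    scores <- ifelse(in_band, 2, ifelse(in_env, 1, 0))
  } else {
    scores <- ifelse(in_band, 1, 0)
    if (!is.na(recipe$exclusion_min)) scores[v < recipe$exclusion_min] <- 0
    if (!is.na(recipe$exclusion_max)) scores[v > recipe$exclusion_max] <- 0
  }
  scores[is.na(v)] <- NA_real_
  env_layer(matrix(scores, nrow = layer$georef$n_rows), layer$georef,
            variable_code = layer$variable_code, units = "score",
            nodata = layer$nodata)
}

#' Weighted sum of reclassified layers
#'
#' Adds the classified layers cell by cell, scaled by their weights, to form
#' the suitability score: the most desired areas get the highest values, up to
#' `max_score = sum(weights)`. Layers on other grids are first resampled onto
#' `target_georef` by nearest-cell lookup (the value of the source cell
#' containing each target cell center), consistent with containing-cell
#' extraction. `target_georef` defaults to the finest-resolution input grid.
#'
#' Nodata propagates conjunctively by default: a cell missing in any layer is
#' missing in the score, so scores are only reported where all evidence
#' exists. `na_policy = "lenient"` instead rescales the sum of the available
#' layers by `max_score / (sum of available weights)`.
#'
#' @param binary_layers List of score [env_layer()]s (from
#'   [reclassify_band()]).
#' @param weights Non-negative weights, one per layer.
#' @param target_georef Optional [grid_georef()] for the output.
#' @param na_policy `"strict"` (default) or `"lenient"`.
#' @return A `suitability_map` object.
#' @export
stack_score <- function(binary_layers, weights = rep(1, length(binary_layers)),
                        target_georef = NULL,
                        na_policy = c("strict", "lenient")) {
  na_policy <- match.arg(na_policy)
  if (length(binary_layers) == 0) stop("no layers to stack", call. = FALSE)
  stopifnot(length(weights) == length(binary_layers), all(weights >= 0))
  if (is.null(target_georef)) {
    cell_area <- vapply(binary_layers, function(l) l$georef$dx * l$georef$dy,
                        numeric(1))
    target_georef <- binary_layers[[which.min(cell_area)]]$georef
  }
  centers <- cell_centers(target_georef)
  vals <- vapply(binary_layers, function(l) {
    if (same_georef(l$georef, target_georef)) as.vector(t(l$values))
    else extract_at_points(l, centers)
  }, numeric(target_georef$n_rows * target_georef$n_cols))
  vals <- matrix(vals, ncol = length(binary_layers))

  w <- matrix(weights, nrow = nrow(vals), ncol = length(weights), byrow = TRUE)
  max_score <- sum(weights)
  if (na_policy == "strict") {
    score <- as.vector(vals %*% weights)  # NA in any layer -> NA
  } else {
    present <- !is.na(vals)
    wsum <- rowSums(w * present)
    score <- rowSums(w * vals, na.rm = TRUE) * ifelse(wsum > 0, max_score / wsum, NA)
    score[wsum == 0] <- NA_real_
  }
  scores <- matrix(score, nrow = target_georef$n_rows,
                   ncol = target_georef$n_cols, byrow = TRUE)
  structure(
    list(georef = target_georef, scores = scores,
         recipes = purrr::map_chr(binary_layers, "variable_code"),
         weights = weights, max_score = max_score),
    class = "suitability_map"
  )
}

#' @export
print.suitability_map <- function(x, ...) {
  cat(sprintf("<suitability_map> %d x %d cells, max score %g\n",
              x$georef$n_rows, x$georef$n_cols, x$max_score))
  cat("  layers:", paste(sprintf("%s (w=%g)", x$recipes, x$weights),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Write a suitability map as an ESRI ASCII grid
#' @param map A `suitability_map`.
#' @param path Output path.
#' @param nodata Nodata sentinel to declare.
#' @return `path`, invisibly.
#' @export
write_suitability <- function(map, path, nodata = -9999) {
  write_env_layer(env_layer(map$scores, map$georef, "suitability",
                            units = "score", nodata = nodata), path)
}

#' Zonal statistics of a suitability map
#'
#' Summarizes the score inside each zone to rank areas: a cell belongs to the
#' zone containing its center (boundary cells to the smaller zone id), and
#' statistics run over non-nodata cells only. Zones capturing no valued cell
#' report `n_cells = 0` with missing statistics. `fraction_at_max` is the
#' share of a zone's valued cells at the map's maximum possible score.
#'
#' @param map A `suitability_map`.
#' @param zones An ecoregion tibble.
#' @return Tibble `zone_id`, `zone_name`, `n_cells`, `mean_score`,
#'   `max_score_observed`, `fraction_at_max`, sorted by `mean_score`
#'   descending, ties and empty zones by `zone_id` ascending.
#' @export
zonal_stats <- function(map, zones) {
  stopifnot(inherits(map, "suitability_map"), nrow(zones) > 0)
  centers <- cell_centers(map$georef)
  centers$score <- as.vector(t(map$scores))
  lab <- assign_ecoregions(
    tibble::tibble(species = "cell", latitude = centers$latitude,
                   longitude = centers$longitude),
    zones, snap_tolerance = 0
  )
  centers$zone_id <- lab$eco_id
  valued <- dplyr::filter(centers, !is.na(.data$zone_id), !is.na(.data$score))
  stats <- if (nrow(valued) == 0) {
    tibble::tibble(zone_id = integer(), n_cells = integer(),
                   mean_score = numeric(), max_score_observed = numeric(),
                   fraction_at_max = numeric())
  } else {
    valued |>
      dplyr::group_by(zone_id = .data$zone_id) |>
      dplyr::summarise(
        n_cells = dplyr::n(),
        mean_score = mean(.data$score),
        max_score_observed = max(.data$score),
        fraction_at_max = mean(.data$score == map$max_score),
        .groups = "drop"
      )
  }
  out <- tibble::tibble(zone_id = zones$eco_id, zone_name = zones$eco_name) |>
    dplyr::left_join(stats, by = "zone_id") |>
    dplyr::mutate(n_cells = dplyr::coalesce(.data$n_cells, 0L)) |>
    dplyr::arrange(dplyr::desc(.data$mean_score), .data$zone_id)
  out
}
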