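#' Linear-interpolation sample quantile
#'
#' The percentile definition used throughout the envelope tables: with sorted
#' values \eqn{x_{(1)} \le \dots \le x_{(n)}} and \eqn{h = (n-1)p + 1}, the
#' quantile is \eqn{x_{(\lfloor h \rfloor)} + (h - \lfloor h \rfloor)
#' (x_{(\lfloor h \rfloor + 1)} - x_{(\lfloor h \rfloor)})}. This is the
#' default of common statistical environments (R's type 7), so envelopes match
#' what a dplyr `summarise()` over the same records would produce.
#'
#' @param values Non-empty numeric vector, all finite.
#' @param p Probability (or vector of probabilities) in \[0, 1\].
#' @return Quantile value(s).
#' @examples
#' niche_quantile(c(1, 2, 3, 4, 5), 0.25)  # 2
#' @export
niche_quantile <- function(values, p) {
  if (length(values) == 0) stop("quantile of an empty sample", call. = FALSE)
  if (any(!is.finite(values))) stop("values must all be finite", call. = FALSE)
  stopifnot(all(p >= 0 & p <= 1))
  unname(stats::quantile(values, probs = p, type = 7, names = FALSE))
}

#' Extract environmental values for labelled occurrences
#'
#' Runs [extract_at_points()] for every layer and stacks the results into one
#' long table, one row per (record, variable) — the input that
#' [summarize_niche()] consumes. Each variable is extracted independently, so
#' a record over a coastal nodata cell of one layer still contributes to the
#' others; missing values are kept as `NA` rows here and excluded per variable
#' downstream.
#'
#' @param occs An occurrence tibble, ideally already carrying `eco_id` /
#'   `eco_name` from [assign_ecoregions()].
#' @param layers A list of [env_layer()] objects.
#' @return Tibble with columns `species`, `eco_id`, `eco_name`,
#'   `variable_code`, `units`, `value`.
#' @export
extract_env_table <- function(occs, layers) {
  stopifnot(length(layers) > 0)
  eco_id <- if ("eco_id" %in% names(occs)) occs$eco_id else rep(NA_integer_, nrow(occs))
  eco_name <- if ("eco_name" %in% names(occs)) occs$eco_name else rep(NA_character_, nrow(occs))
  purrr::map_dfr(layers, function(ly) {
    tibble::tibble(
      species = occs$species,
      eco_id = eco_id,
      eco_name = eco_name,
      variable_code = ly$variable_code,
      units = ly$units,
      value = extract_at_points(ly, occs)
    )
  })
}

#' Five-number realized-niche envelopes by species and ecoregion
#'
#' For every (species, ecoregion, variable) group with at least one non-missing
#' extracted value, computes the minimum, 25th percentile, arithmetic mean,
#' 75th percentile and maximum of the values — the envelope summarizing where
#' the species has actually been observed. Missing values are excluded per
#' variable and `n_obs` is the per-variable non-missing count. Groups whose
#' every value is missing, and records without an ecoregion, produce no row.
#'
#' @param extractions Long table from [extract_env_table()] (columns `species`,
#'   `eco_id`, `variable_code`, `value`; `eco_name`/`units` carried through
#'   when present).
#' @return A `niche_summary` tibble: `species`, `eco_id`, `eco_name`,
#'   `variable_code`, `units`, `n_obs`, `min`, `p25`, `mean`, `p75`, `max`,
#'   sorted by species, eco_id, variable_code. Every row satisfies
#'   `min <= p25 <= p75 <= max` and `min <= mean <= max`.
#' @export
summarize_niche <- function(extractions) {
  stopifnot(all(c("species", "eco_id", "variable_code", "value") %in%
                  names(extractions)))
  if (!"eco_name" %in% names(extractions)) extractions$eco_name <- NA_character_
  if (!"units" %in% names(extractions)) extractions$units <- NA_character_
  out <- extractions |>
    dplyr::filter(!is.na(.data$value), !is.na(.data$eco_id)) |>
    dplyr::group_by(.data$species, .data$eco_id, .data$variable_code) |>
    dplyr::summarise(
      eco_name = dplyr::first(.data$eco_name),
      units = dplyr::first(.data$units),
      n_obs = dplyr::n(),
      min = min(.data$value),
      p25 = niche_quantile(.data$value, 0.25),
      mean = mean(.data$value),
      p75 = niche_quantile(.data$value, 0.75),
      max = max(.data$value),
      .groups = "drop"
    ) |>
    dplyr::select("species", "eco_id", "eco_name", "variable_code", "units",
                  "n_obs", "min", "p25", "mean", "p75", "max") |>
    dplyr::arrange(.data$species, .data$eco_id, .data$variable_code)
  class(out) <- unique(c("niche_summary", class(out)))
  out
}

#' Occurrence counts per species-ecoregion pair
#'
#' The count basis for [filter_min_observations()]: number of occurrence
#' records assigned to each (species, ecoregion) pair, before any per-variable
#' missing-value exclusion. Unassigned records are skipped.
#'
#' @param occs A labelled occurrence tibble (after [assign_ecoregions()]).
#' @return Tibble `species`, `eco_id`, `n_records`.
#' @export
pair_counts <- function(occs) {
  occs |>
    tibble::as_tibble() |>
    dplyr::filter(!is.na(.data$eco_id)) |>
    dplyr::count(.data$species, .data$eco_id, name = "n_records")
}

#' Apply the minimum-observation filter to envelope rows
#'
#' Keeps only species-ecoregion pairs with strictly more than `threshold`
#' occurrence records (the data-quality rule "more than 10 observations", so a
#' pair with exactly 10 records is dropped). All variables of a dropped pair
#' are dropped together. The filter counts occurrence records per pair, not
#' per-variable non-missing extractions: a surviving row may therefore report
#' an `n_obs` at or below the threshold for a sparse layer.
#'
#' @param rows A `niche_summary` tibble.
#' @param count_basis Per-pair record counts from [pair_counts()].
#' @param threshold Minimum (exclusive) record count; default 10.
#' @return The filtered `niche_summary` tibble.
#' @export
filter_min_observations <- function(rows, count_basis, threshold = 10) {
  stopifnot(threshold >= 0,
            all(c("species", "eco_id", "n_records") %in% names(count_basis)))
  keep <- dplyr::filter(count_basis, .data$n_records > threshold)
  out <- dplyr::semi_join(rows, keep, by = c("species", "eco_id"))
  class(out) <- unique(c("niche_summary", class(out)))
  out
}

#' Write a niche-summary table with a metadata sidecar
#'
#' The CSV holds one row per (species, ecoregion, variable) with the columns
#' of [summarize_niche()]; the JSON sidecar (`<path>.meta.json`) records layer
#' provenance, occurrence provenance and filter settings so the table is
#' self-describing.
#'
#' @param rows A `niche_summary` tibble.
#' @param path Output CSV path.
#' @param metadata Named list to embed in the sidecar (layer catalogue,
#'   access dates, filter settings). Optional.
#' @return `path`, invisibly.
#' @export
write_niche_summary <- function(rows, path, metadata = list()) {
  readr::write_csv(tibble::as_tibble(rows), path, na = "", progress = FALSE)
  side <- c(list(columns = names(rows), n_rows = nrow(rows)), metadata)
  jsonlite::write_json(side, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
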