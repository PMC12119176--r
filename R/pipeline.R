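#' Pipeline configuration
#'
#' Collects every input path and setting for [run_pipeline()]. Serializable to
#' YAML ([write_pipeline_config()], [read_pipeline_config()]) so a run is
#' reproducible from one file; all randomness in a run flows from `seed`.
#'
#' @param occurrences Path to the occurrence CSV/TSV.
#' @param layers List of layer entries, each `list(path, variable_code,
#'   units)`; the first layer is the land-removal reference unless
#'   `land_reference` names another `variable_code`.
#' @param ecoregions Path to the ecoregion GeoJSON.
#' @param output_dir Directory for all outputs.
#' @param taxon_order Order retained by the taxon filter.
#' @param min_observations Per-pair record threshold (strictly-greater rule).
#' @param snap_tolerance Ecoregion snap distance, degrees.
#' @param band_mode `"iqr"` or `"range"` for suitability recipes.
#' @param weights Named (by `variable_code`) or unnamed weights for scoring;
#'   `NULL` = all 1.
#' @param suitability_for Optional `list(species =, eco_id =)` selecting the
#'   envelope that drives the optional scoring stage; `NULL` skips scoring.
#' @param land_reference `variable_code` of the reference ocean layer.
#' @param drop_duplicates Forwarded to [read_occurrences()].
#' @param seed Integer master seed.
#' @param accessed Access-date text recorded in metadata sidecars.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(occurrences, layers, ecoregions, output_dir,
                            taxon_order = "Laminariales", min_observations = 10,
                            snap_tolerance = 0, band_mode = "iqr",
                            weights = NULL, suitability_for = NULL,
                            land_reference = NULL, drop_duplicates = FALSE,
                            seed = 1, accessed = NA_character_) {
  stopifnot(min_observations >= 0, snap_tolerance >= 0,
            band_mode %in% c("iqr", "range"))
  if (!is.null(weights)) stopifnot(all(unlist(weights) >= 0))
  paths <- c(occurrences, ecoregions, vapply(layers, `[[`, "", "path"))
  if (anyDuplicated(paths)) stop("referenced paths must be distinct", call. = FALSE)
  structure(
    list(occurrences = occurrences, layers = layers, ecoregions = ecoregions,
         output_dir = output_dir, taxon_order = taxon_order,
         min_observations = min_observations, snap_tolerance = snap_tolerance,
         band_mode = band_mode, weights = weights,
         suitability_for = suitability_for, land_reference = land_reference,
         drop_duplicates = drop_duplicates, seed = as.integer(seed),
         accessed = accessed),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration (YAML)
#' @param path YAML file.
#' @return For `read_pipeline_config()`, a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full niche-envelope pipeline
#'
#' Executes read -> taxon filter -> land removal -> ecoregion assignment ->
#' extraction -> minimum-observation filter -> envelope summary, and, when the
#' config selects a species-ecoregion envelope, reclassification -> weighted
#' stacking -> zonal statistics. Every stage's input/output/rejected counts
#' are logged to the console and to `run_log.txt`; tabular outputs are written
#' without timestamps, so identical config + seed gives bit-identical tables.
#' Any stage error aborts the run, removes partial outputs, and names the
#' failing stage.
#'
#' Outputs in `config$output_dir`: `occurrences_labelled.csv`,
#' `rejections.csv`, `extractions.csv`, `niche_summary.csv` (+
#' `.meta.json` sidecar), `run_summary.csv`, and with scoring enabled
#' `suitability.asc` and `zonal_stats.csv`.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress console stage messages.
#' @return Run-summary tibble (`stage`, `n_in`, `n_out`, `n_rejected`), with
#'   output paths in `attr(, "paths")`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  log_lines <- character()
  stages <- list()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }
  note_stage <- function(stage, n_in, n_out) {
    stages[[length(stages) + 1]] <<- tibble::tibble(
      stage = stage, n_in = n_in, n_out = n_out, n_rejected = n_in - n_out)
    say("[%s] in=%d out=%d rejected=%d", stage, n_in, n_out, n_in - n_out)
  }
  emit <- function(path) written <<- c(written, path)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("pipeline stage `", stage, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  set.seed(config$seed)

  occs <- run_stage("read", {
    raw_lines <- length(readr::read_lines(config$occurrences)) - 1L
    o <- read_occurrences(config$occurrences,
                          drop_duplicates = config$drop_duplicates,
                          accessed = config$accessed)
    note_stage("read", raw_lines, nrow(o))
    o
  })

  occs <- run_stage("filter_taxon", {
    o <- filter_taxon(occs, config$taxon_order)
    note_stage("filter_taxon", nrow(occs), nrow(o))
    o
  })

  layers <- run_stage("read_layers", {
    ls <- lapply(config$layers, function(e) {
      read_env_layer(e$path, variable_code = e$variable_code, units = e$units)
    })
    names(ls) <- vapply(ls, function(l) l$variable_code, character(1))
    say("[read_layers] %d layers: %s", length(ls), paste(names(ls), collapse = ", "))
    ls
  })

  occs <- run_stage("drop_land", {
    ref_code <- config$land_reference %||% names(layers)[[1]]
    ref <- layers[[ref_code]]
    if (is.null(ref)) stop("land_reference layer `", ref_code, "` not found")
    o <- drop_land_points(occs, ref)
    note_stage("drop_land", nrow(occs), nrow(o))
    o
  })

  occs <- run_stage("assign_ecoregions", {
    regions <- load_ecoregions(config$ecoregions)
    o <- assign_ecoregions(occs, regions, snap_tolerance = config$snap_tolerance)
    note_stage("assign_ecoregions", nrow(o), sum(!is.na(o$eco_id)))
    attr(o, "regions") <- regions
    o
  })
  regions <- attr(occs, "regions")

  extractions <- run_stage("extract", {
    ex <- extract_env_table(occs, layers)
    say("[extract] %d record x variable values (%d missing)",
        nrow(ex), sum(is.na(ex$value)))
    ex
  })

  summary_rows <- run_stage("summarize", {
    counts <- pair_counts(occs)
    rows <- summarize_niche(extractions)
    kept <- filter_min_observations(rows, counts, config$min_observations)
    note_stage("min_observation_filter",
               nrow(dplyr::distinct(rows, .data$species, .data$eco_id)),
               nrow(dplyr::distinct(kept, .data$species, .data$eco_id)))
    say("[summarize] %d envelope rows", nrow(kept))
    if (nrow(kept) == 0) warning("no species-ecoregion pair passed the ",
                                 "minimum-observation filter", call. = FALSE)
    kept
  })

  run_stage("write_tables", {
    p <- file.path(out_dir, "occurrences_labelled.csv")
    readr::write_csv(tibble::as_tibble(occs), p, na = "", progress = FALSE); emit(p)
    p <- file.path(out_dir, "rejections.csv")
    write_rejections(occs, p); emit(p)
    p <- file.path(out_dir, "extractions.csv")
    readr::write_csv(extractions, p, na = "", progress = FALSE); emit(p)
    p <- file.path(out_dir, "niche_summary.csv")
    write_niche_summary(summary_rows, p, metadata = list(
      occurrences = list(source = config$occurrences, accessed = config$accessed),
      layers = config$layers,
      filter = list(taxon_order = config$taxon_order,
                    min_observations = config$min_observations,
                    rule = "strictly greater"),
      snap_tolerance = config$snap_tolerance,
      seed = config$seed
    ))
    emit(p); emit(paste0(p, ".meta.json"))
  })

  if (!is.null(config$suitability_for)) {
    run_stage("suitability", {
      sel <- config$suitability_for
      rows <- dplyr::filter(summary_rows, .data$species == sel$species,
                            .data$eco_id == sel$eco_id)
      if (nrow(rows) == 0) {
        stop("no envelope rows for ", sel$species, " / eco_id ", sel$eco_id)
      }
      w <- if (is.null(config$weights)) rep(1, nrow(rows))
           else if (!is.null(names(config$weights)))
             unlist(config$weights)[rows$variable_code]
           else rep_len(unlist(config$weights), nrow(rows))
      recipes <- recipe_from_summary(rows, mode = config$band_mode, weight = w)
      binaries <- lapply(seq_len(nrow(recipes)), function(i) {
        reclassify_band(layers[[recipes$variable_code[i]]], recipes[i, ])
      })
      smap <- stack_score(binaries, weights = recipes$weight)
      p <- file.path(out_dir, "suitability.asc")
      write_suitability(smap, p); emit(p)
      zs <- zonal_stats(smap, regions)
      p <- file.path(out_dir, "zonal_stats.csv")
      readr::write_csv(zs, p, na = "", progress = FALSE); emit(p)
      say("[suitability] %s / eco %d: max score %g, best zone %s",
          sel$species, sel$eco_id, smap$max_score,
          zs$zone_name[[1]])
    })
  }

  run_summary <- dplyr::bind_rows(stages)
  p <- file.path(out_dir, "run_summary.csv")
  readr::write_csv(run_summary, p, na = "", progress = FALSE); emit(p)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  attr(run_summary, "paths") <- written
  run_summary
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Record-distribution diagnostics
#'
#' Tallies labelled occurrence records by ecoregion and by genus (each with a
#' `log10_n` column, matching how strongly skewed archives are usually
#' displayed) and reports the share of all records held by the top-`k`
#' ecoregions — the geographic-bias headline (in the global kelp archive, two
#' Californian ecoregions hold the bulk of all records).
#'
#' @param occs A labelled occurrence tibble (after [assign_ecoregions()]).
#' @param k How many top ecoregions the share is computed over.
#' @return List of tibbles: `per_ecoregion` (`eco_id`, `eco_name`,
#'   `n_records`, `log10_n`), `per_genus` (`genus`, `n_records`, `log10_n`),
#'   `top_share` (`k`, `n_top`, `n_total`, `share_pct`).
#' @export
report_record_distribution <- function(occs, k = 2) {
  occs <- tibble::as_tibble(occs)
  per_eco <- occs |>
    dplyr::filter(!is.na(.data$eco_id)) |>
    dplyr::count(.data$eco_id, .data$eco_name, name = "n_records") |>
    dplyr::mutate(log10_n = log10(.data$n_records)) |>
    dplyr::arrange(dplyr::desc(.data$n_records))
  per_genus <- occs |>
    dplyr::count(.data$genus, name = "n_records") |>
    dplyr::mutate(log10_n = log10(.data$n_records)) |>
    dplyr::arrange(dplyr::desc(.data$n_records))
  top_share <- if (nrow(per_eco) == 0) {
    tibble::tibble(k = integer(), n_top = integer(), n_total = integer(),
                   share_pct = numeric())
  } else {
    n_top <- sum(utils::head(per_eco$n_records, k))
    n_total <- sum(per_eco$n_records)
    tibble::tibble(k = as.integer(k), n_top = n_top, n_total = n_total,
                   share_pct = 100 * n_top / n_total)
  }
  list(per_ecoregion = per_eco, per_genus = per_genus, top_share = top_share)
}
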