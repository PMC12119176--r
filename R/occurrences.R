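#' Default GBIF column mapping
#'
#' Maps the semantic occurrence fields onto the column names of a GBIF simple
#' download. Override entries to ingest other delimited exports; set an entry
#' to `NA` to skip an optional field (`genus`, `order`, `event_year`,
#' `source_id`).
#'
#' @return Named character vector: semantic field -> column name.
#' @export
gbif_column_map <- function() {
  c(species = "species", genus = "genus", order = "order",
    latitude = "decimalLatitude", longitude = "decimalLongitude",
    event_year = "year", source_id = "gbifID")
}

occ_fields <- c("species", "genus", "order", "latitude", "longitude",
                "event_year", "source_id")

# Reattach occurrence bookkeeping (rejection log, provenance) after base
# subsetting; dplyr verbs drop bespoke attributes, so the package's own
# record-dropping steps go through this.
keep_occ_attrs <- function(new, old) {
  attr(new, "rejections") <- attr(old, "rejections")
  attr(new, "provenance") <- attr(old, "provenance")
  class(new) <- unique(c("occ_tbl", class(new)))
  new
}

empty_rejections <- function() {
  tibble::tibble(row_number = integer(), reason_code = character(),
                 raw_line = character())
}

append_rejections <- function(occs, rej) {
  cur <- attr(occs, "rejections")
  if (is.null(cur)) cur <- empty_rejections()
  attr(occs, "rejections") <- dplyr::bind_rows(cur, rej)
  occs
}

#' Rejection log of an occurrence set
#'
#' Every row dropped during reading, land removal or ecoregion assignment is
#' accounted for here with a reason code, so `records + rejections` always
#' equals the rows that went in.
#'
#' @param occs An occurrence tibble.
#' @return Tibble with columns `row_number`, `reason_code`, `raw_line`.
#' @export
rejections <- function(occs) {
  r <- attr(occs, "rejections")
  if (is.null(r)) empty_rejections() else r
}

#' Provenance of an occurrence set
#' @param occs An occurrence tibble.
#' @return List with `source` and `accessed`.
#' @export
provenance <- function(occs) attr(occs, "provenance")

#' Read occurrence records from a delimited file
#'
#' Reads a GBIF-style occurrence export (comma- or tab-delimited, autodetected
#' from the header line), validates coordinates and species names, and routes
#' every unusable row to the rejection log with a reason code — nothing is
#' silently dropped. Records missing the year are kept; year is provenance,
#' not a filter.
#'
#' Reason codes: `coordinate_unparseable` (non-numeric or empty coordinate),
#' `coordinate_out_of_range` (latitude outside \[-90, 90\] or longitude outside
#' \[-180, 180\]), `missing_species_name` (blank after whitespace trimming),
#' `exact_duplicate` (only when `drop_duplicates = TRUE`).
#'
#' @param path Delimited text file with a header row, UTF-8.
#' @param column_map See [gbif_column_map()].
#' @param drop_duplicates Drop rows whose (species, latitude, longitude,
#'   event_year) exactly repeat an earlier row? Off by default: envelope
#'   statistics are defined over raw observations.
#' @param accessed Free-text access date recorded in the provenance.
#' @return A tibble of clean records (columns `species`, `genus`, `order`,
#'   `latitude`, `longitude`, `event_year`, `source_id`) carrying the
#'   rejection log ([rejections()]) and provenance ([provenance()]).
#' @export
read_occurrences <- function(path, column_map = gbif_column_map(),
                             drop_duplicates = FALSE, accessed = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  if (length(lines) == 0) stop("empty file (no header row): ", path, call. = FALSE)
  delim <- if (grepl("\t", lines[[1]])) "\t" else ","

  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           na = character(), trim_ws = FALSE, progress = FALSE,
                           show_col_types = FALSE)
  required <- c("species", "latitude", "longitude")
  for (f in required) {
    cm <- column_map[[f]]
    if (is.na(cm) || !cm %in% names(raw)) {
      stop("column for `", f, "` (mapped to \"", cm, "\") not found in header",
           call. = FALSE)
    }
  }
  get_col <- function(f) {
    cm <- column_map[[f]]
    if (!is.null(cm) && !is.na(cm) && cm %in% names(raw)) raw[[cm]]
    else rep(NA_character_, nrow(raw))
  }

  species <- trimws(get_col("species"))
  lat <- suppressWarnings(as.numeric(get_col("latitude")))
  lon <- suppressWarnings(as.numeric(get_col("longitude")))

  reason <- rep(NA_character_, nrow(raw))
  bad_parse <- is.na(lat) | is.na(lon)
  reason[bad_parse] <- "coordinate_unparseable"
  bad_range <- !bad_parse & (lat < -90 | lat > 90 | lon < -180 | lon > 180)
  reason[bad_range] <- "coordinate_out_of_range"
  no_species <- is.na(reason) & (is.na(species) | species == "")
  reason[no_species] <- "missing_species_name"

  recs <- tibble::tibble(
    species = species,
    genus = trimws(get_col("genus")),
    order = trimws(get_col("order")),
    latitude = lat,
    longitude = lon,
    event_year = suppressWarnings(as.integer(get_col("event_year"))),
    source_id = get_col("source_id")
  )
  keep <- is.na(reason)
  out <- recs[keep, , drop = FALSE]
  rej <- tibble::tibble(
    row_number = which(!keep),
    reason_code = reason[!keep],
    raw_line = lines[which(!keep) + 1L]
  )
  if (drop_duplicates && nrow(out) > 0) {
    dup <- duplicated(out[, c("species", "latitude", "longitude", "event_year")])
    if (any(dup)) {
      rej <- dplyr::bind_rows(rej, tibble::tibble(
        row_number = which(keep)[dup],
        reason_code = "exact_duplicate",
        raw_line = lines[which(keep)[dup] + 1L]
      ))
      out <- out[!dup, , drop = FALSE]
    }
  }
  if (nrow(out) == 0 && nrow(raw) > 0) {
    warning("no parseable occurrence rows in ", path, call. = FALSE)
  }
  attr(out, "rejections") <- dplyr::arrange(rej, row_number)
  attr(out, "provenance") <- list(source = path, accessed = accessed)
  class(out) <- unique(c("occ_tbl", class(out)))
  out
}

#' Write occurrence records as CSV
#'
#' Writes the seven semantic columns with GBIF-style headers so the file can
#' be re-read by [read_occurrences()] with the default column map
#' (round-trip safe).
#'
#' @param occs An occurrence tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occs, path) {
  out <- tibble::tibble(
    species = occs$species, genus = occs$genus, order = occs$order,
    decimalLatitude = occs$latitude, decimalLongitude = occs$longitude,
    year = occs$event_year, gbifID = occs$source_id
  )
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write the rejection log
#' @param occs An occurrence tibble.
#' @param path Output path (CSV: `row_number`, `reason_code`, `raw_line`).
#' @return `path`, invisibly.
#' @export
write_rejections <- function(occs, path) {
  readr::write_csv(rejections(occs), path, na = "", progress = FALSE)
  invisible(path)
}

#' Keep records of one taxonomic order
#'
#' Case-insensitive match on the `order` column (kelps are the order
#' Laminariales); records with a missing order are dropped. Idempotent.
#'
#' @param occs An occurrence tibble.
#' @param order_name Order to retain, e.g. `"Laminariales"`.
#' @return The filtered occurrence tibble (log and provenance preserved).
#' @export
filter_taxon <- function(occs, order_name) {
  keep <- !is.na(occs$order) & tolower(occs$order) == tolower(order_name)
  keep_occ_attrs(occs[keep, , drop = FALSE], occs)
}
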