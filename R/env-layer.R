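#' Environmental layer
#'
#' A single-variable georeferenced grid. Values are stored as a numeric matrix
#' (row 1 = northmost row); cells with no valid measurement (land, out of
#' domain) are `NA` internally and are written out as the `nodata` sentinel.
#'
#' @param values Numeric matrix, `n_rows x n_cols`, `NA` for nodata.
#' @param georef A [grid_georef()] matching `dim(values)`.
#' @param variable_code Short layer code (e.g. `"bo_sst_x"`).
#' @param units Measurement units (e.g. `"°C"` for sea-surface
#'   temperature, `"PSS"` for salinity).
#' @param nodata Sentinel written for `NA` cells on export.
#' @return An `env_layer` object.
#' @export
env_layer <- function(values, georef, variable_code, units = "", nodata = -9999) {
  stopifnot(is.matrix(values), inherits(georef, "grid_georef"))
  if (!all(dim(values) == c(georef$n_rows, georef$n_cols))) {
    stop("`values` must be a ", georef$n_rows, " x ", georef$n_cols,
         " matrix to match `georef`", call. = FALSE)
  }
  if (any(is.infinite(values))) {
    stop("layer values must be finite or NA", call. = FALSE)
  }
  structure(
    list(variable_code = variable_code, units = units, georef = georef,
         values = values, nodata = as.numeric(nodata)),
    class = "env_layer"
  )
}

#' @export
print.env_layer <- function(x, ...) {
  n_ok <- sum(!is.na(x$values))
  cat(sprintf("<env_layer> %s [%s]: %d x %d cells (%d valued)\n",
              x$variable_code, x$units, x$georef$n_rows, x$georef$n_cols, n_ok))
  if (n_ok > 0) {
    cat(sprintf("  range %g .. %g\n",
                min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  }
  invisible(x)
}

#' Read an environmental layer from an ESRI ASCII grid
#'
#' Reads a single-band ESRI ASCII grid (`.asc`) in geographic (lon/lat)
#' coordinates. The header must carry `ncols`, `nrows`, `xllcorner`/`xllcenter`,
#' `yllcorner`/`yllcenter` and `cellsize`; `NODATA_value` is honoured when
#' present, else `nodata` is used as the sentinel. GeoTIFF input is not
#' supported; export rasters to ASCII grid first (any GIS can).
#'
#' @param path Path to the `.asc` file.
#' @param variable_code Layer code to record (e.g. `"bo_sst_x"`).
#' @param units Units to record (e.g. `"°C"`).
#' @param nodata Fallback nodata sentinel for files lacking `NODATA_value`.
#' @return An [env_layer()].
#' @export
read_env_layer <- function(path, variable_code, units = "", nodata = -9999) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    stop("GeoTIFF input is not supported; convert the layer to an ESRI ASCII ",
         "grid (.asc)", call. = FALSE)
  }
  lines <- readLines(path, n = 8L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z_]+)\\s+(-?[0-9.eE+-]+)\\s*$", ln))[[1]]
    if (length(m) == 3) {
      hdr[[tolower(m[2])]] <- as.numeric(m[3])
      n_hdr <- n_hdr + 1L
    } else break
  }
  need <- c("ncols", "nrows")
  if (!all(need %in% names(hdr)) || is.null(hdr$cellsize) ||
      (is.null(hdr$xllcorner) && is.null(hdr$xllcenter)) ||
      (is.null(hdr$yllcorner) && is.null(hdr$yllcenter))) {
    stop("not a georeferenced ESRI ASCII grid (header incomplete): ", path,
         call. = FALSE)
  }
  n_cols <- as.integer(hdr$ncols)
  n_rows <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  sentinel <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else nodata

  vals <- scan(path, what = numeric(), skip = n_hdr, quiet = TRUE)
  if (length(vals) != n_rows * n_cols) {
    stop("grid body has ", length(vals), " values; expected ",
         n_rows * n_cols, " (multi-band or truncated file?)", call. = FALSE)
  }
  m <- matrix(vals, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  m[m == sentinel] <- NA_real_
  g <- grid_georef(west = xll, north = yll + n_rows * cs,
                   dx = cs, dy = cs, n_rows = n_rows, n_cols = n_cols)
  env_layer(m, g, variable_code = variable_code, units = units,
            nodata = sentinel)
}

#' Write an environmental layer as an ESRI ASCII grid
#'
#' Requires square cells (`dx == dy`), as the ASCII grid format carries a
#' single `cellsize`. Values are written at full double precision so a
#' write/read round trip is exact.
#'
#' @param layer An [env_layer()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_env_layer <- function(layer, path) {
  stopifnot(inherits(layer, "env_layer"))
  g <- layer$georef
  if (abs(g$dx - g$dy) > 1e-12) {
    stop("ESRI ASCII grids need square cells (dx == dy)", call. = FALSE)
  }
  hdr <- c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.17g", g$west),
    sprintf("yllcorner %.17g", georef_south(g)),
    sprintf("cellsize %.17g", g$dx),
    sprintf("NODATA_value %.17g", layer$nodata)
  )
  m <- layer$values
  m[is.na(m)] <- layer$nodata
  body <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Extract layer values at points
#'
#' Containing-cell (nearest-cell) lookup, no interpolation: each point takes
#' the value of the unique cell containing it under the grid's half-open
#' convention. Points outside the grid, or over nodata cells, yield `NA`.
#'
#' @param layer An [env_layer()].
#' @param points A data frame with `latitude` and `longitude` columns, or a
#'   two-column matrix `(latitude, longitude)`.
#' @return Numeric vector of values, in input order; `NA` means missing.
#' @examples
#' g <- grid_georef(0, 2, 1, 1, 2, 2)
#' sst <- env_layer(matrix(c(10, 11, 12, 13), 2, 2, byrow = TRUE), g, "bo_sst_x")
#' extract_at_points(sst, data.frame(latitude = 1.5, longitude = 0.5))
#' @export
extract_at_points <- function(layer, points) {
  stopifnot(inherits(layer, "env_layer"))
  if (is.matrix(points)) {
    points <- data.frame(latitude = points[, 1], longitude = points[, 2])
  }
  stopifnot(all(c("latitude", "longitude") %in% names(points)))
  idx <- locate_cells(layer$georef, points$longitude, points$latitude)
  out <- rep(NA_real_, nrow(points))
  ok <- !is.na(idx$row) & !is.na(idx$col)
  out[ok] <- layer$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Remove land-based occurrence records
#'
#' Drops records that fall on nodata cells (or outside the bounds) of a
#' designated reference ocean layer, on the reading that nodata on an
#' ocean-only layer marks land or out-of-domain. Dropped records are appended
#' to the rejection log with reason `"land_or_out_of_domain"`. Idempotent.
#'
#' @param occs An occurrence tibble (see [read_occurrences()]).
#' @param reference An [env_layer()] whose nodata cells denote land.
#' @return The surviving occurrences, rejection log updated.
#' @export
drop_land_points <- function(occs, reference) {
  stopifnot(inherits(reference, "env_layer"))
  vals <- extract_at_points(reference, occs)
  keep <- !is.na(vals)
  dropped <- occs[!keep, , drop = FALSE]
  out <- keep_occ_attrs(occs[keep, , drop = FALSE], occs)
  if (nrow(dropped) > 0) {
    rej <- tibble::tibble(
      row_number = which(!keep),
      reason_code = "land_or_out_of_domain",
      raw_line = paste(dropped$species, dropped$latitude, dropped$longitude,
                       sep = ",")
    )
    out <- append_rejections(out, rej)
  }
  out
}
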