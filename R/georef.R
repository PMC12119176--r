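#' Grid georeference
#'
#' Describes the placement of a regular lon/lat grid. Cell `(r, c)` (1-based)
#' covers longitudes `[west + (c-1)*dx, west + c*dx)` and latitudes
#' `(north - r*dy, north - (r-1)*dy]`; row 1 is the northmost row. This
#' half-open convention is used everywhere a point is matched to a cell, so a
#' point on a shared cell edge belongs to exactly one cell.
#'
#' @param west Western edge of the grid, decimal degrees.
#' @param north Northern edge of the grid, decimal degrees.
#' @param dx Cell width, degrees per column (> 0).
#' @param dy Cell height, degrees per row (> 0).
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @return A `grid_georef` object.
#' @examples
#' g <- grid_georef(west = -10, north = 10, dx = 0.5, dy = 0.5,
#'                  n_rows = 40, n_cols = 40)
#' @export
grid_georef <- function(west, north, dx, dy, n_rows, n_cols) {
  stopifnot(is.numeric(west), is.numeric(north), dx > 0, dy > 0,
            n_rows >= 1, n_cols >= 1)
  structure(
    list(west = as.numeric(west), north = as.numeric(north),
         dx = as.numeric(dx), dy = as.numeric(dy),
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
    class = "grid_georef"
  )
}

#' @export
print.grid_georef <- function(x, ...) {
  cat(sprintf("<grid_georef> %d rows x %d cols, cell %g x %g deg\n",
              x$n_rows, x$n_cols, x$dx, x$dy))
  cat(sprintf("  lon [%g, %g), lat (%g, %g]\n",
              x$west, georef_east(x), georef_south(x), x$north))
  invisible(x)
}

georef_east <- function(g) g$west + g$n_cols * g$dx
georef_south <- function(g) g$north - g$n_rows * g$dy

same_georef <- function(a, b, tol = 1e-9) {
  all(abs(c(a$west - b$west, a$north - b$north, a$dx - b$dx, a$dy - b$dy)) < tol) &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

#' Cell-center coordinates of a grid
#'
#' @param georef A [grid_georef()].
#' @return A tibble with columns `row`, `col`, `longitude`, `latitude`, one row
#'   per cell in row-major order (row 1 = northmost).
#' @export
cell_centers <- function(georef) {
  stopifnot(inherits(georef, "grid_georef"))
  rc <- expand.grid(col = seq_len(georef$n_cols), row = seq_len(georef$n_rows))
  tibble::tibble(
    row = rc$row,
    col = rc$col,
    longitude = georef$west + (rc$col - 0.5) * georef$dx,
    latitude = georef$north - (rc$row - 0.5) * georef$dy
  )
}

# Normalize longitudes so the antimeridian is unambiguous: values outside
# [-180, 180) (in particular exactly +180) are wrapped into that interval.
# Longitudes already inside are untouched, so grids on arbitrary sub-domains
# are unaffected.
normalize_lon <- function(lon) {
  out <- lon
  wrap <- !is.na(lon) & (lon >= 180 | lon < -180)
  out[wrap] <- ((lon[wrap] + 180) %% 360) - 180
  out
}

# Map points to 1-based (row, col) under the half-open convention; NA where a
# point falls outside the grid. floor() gives the candidate index; because
# floating-point division can disagree with the defining inequalities on exact
# cell edges, the candidate is checked (and its two neighbours tried) against
# the inequalities themselves, so locate_cells() agrees with a literal
# containment scan.
locate_cells <- function(georef, longitude, latitude) {
  g <- georef
  lon <- normalize_lon(longitude)
  lat <- latitude

  col_ok <- function(ci) {
    !is.na(ci) & ci >= 1 & ci <= g$n_cols &
      (g$west + (ci - 1) * g$dx) <= lon & lon < (g$west + ci * g$dx)
  }
  row_ok <- function(ri) {
    !is.na(ri) & ri >= 1 & ri <= g$n_rows &
      (g$north - ri * g$dy) < lat & lat <= (g$north - (ri - 1) * g$dy)
  }

  ci0 <- floor((lon - g$west) / g$dx) + 1
  ri0 <- floor((g$north - lat) / g$dy) + 1
  col <- rep(NA_integer_, length(lon))
  row <- rep(NA_integer_, length(lat))
  for (off in c(0, -1, 1)) {
    cand <- ci0 + off
    hit <- is.na(col) & col_ok(cand)
    col[hit] <- as.integer(cand[hit])
    cand <- ri0 + off
    hit <- is.na(row) & row_ok(cand)
    row[hit] <- as.integer(cand[hit])
  }
  list(row = row, col = col)
}
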