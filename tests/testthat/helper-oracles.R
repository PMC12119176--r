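# Independent oracles, each a literal transcription of the defining rule,
# deliberately sharing no code with the implementation they check.

# Linear-interpolation quantile: h = (n-1)p + 1 over the sorted sample.
oracle_quantile <- function(values, p) {
  x <- sort(values)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}

# Exhaustive containment scan: test every cell's half-open intervals.
# Cell (r, c), 1-based: lon in [west+(c-1)dx, west+c dx), lat in
# (north - r dy, north - (r-1) dy].
oracle_extract <- function(layer, latitude, longitude) {
  g <- layer$georef
  vapply(seq_along(latitude), function(i) {
    lon <- longitude[i]; lat <- latitude[i]
    if (lon >= 180 || lon < -180) lon <- ((lon + 180) %% 360) - 180
    for (r in seq_len(g$n_rows)) {
      for (c in seq_len(g$n_cols)) {
        if (g$west + (c - 1) * g$dx <= lon && lon < g$west + c * g$dx &&
            g$north - r * g$dy < lat && lat <= g$north - (r - 1) * g$dy) {
          return(layer$values[r, c])
        }
      }
    }
    NA_real_
  }, numeric(1))
}

# Even-odd ray casting for a single ring (matrix of lon/lat vertices).
oracle_in_ring <- function(ring, lon, lat) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > lat) != (yj > lat)) {
      x_int <- xi + (lat - yi) / (yj - yi) * (xj - xi)
      if (lon < x_int) inside <- !inside
    }
    j <- i
  }
  inside
}

# Even-odd over all rings of a geometry (holes flip membership).
oracle_in_geometry <- function(geometry, lon, lat) {
  count <- sum(vapply(geometry, function(ring) {
    r <- if (all(ring[1, ] == ring[nrow(ring), ])) ring[-nrow(ring), , drop = FALSE]
         else ring
    oracle_in_ring(r, lon, lat)
  }, logical(1)))
  count %% 2 == 1
}

# Shoelace area of one ring, absolute value.
oracle_ring_area <- function(ring) {
  r <- if (all(ring[1, ] == ring[nrow(ring), ])) ring else rbind(ring, ring[1, ])
  n <- nrow(r)
  abs(sum(r[-n, 1] * r[-1, 2] - r[-1, 1] * r[-n, 2])) / 2
}

# A random valued grid for extraction tests.
random_layer <- function(n_rows, n_cols, west = runif(1, -170, 100),
                         north = runif(1, -40, 80), dx = runif(1, 0.05, 2),
                         dy = runif(1, 0.05, 2), na_frac = 0) {
  g <- grid_georef(west, north, dx, dy, n_rows, n_cols)
  m <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  if (na_frac > 0) m[sample.int(length(m), floor(na_frac * length(m)))] <- NA
  env_layer(m, g, "test_var", "unitless")
}

# Records only: drop the bookkeeping attributes so two occurrence sets can be
# compared as plain tables.
plain_records <- function(x) {
  x <- tibble::as_tibble(x)
  attr(x, "rejections") <- NULL
  attr(x, "provenance") <- NULL
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}

# A bare occurrence tibble for unit tests that skip the reader.
occ_fixture <- function(species, latitude, longitude,
                        genus = sub(" .*", "", species),
                        order = "Laminariales") {
  out <- tibble::tibble(species = species, genus = genus, order = order,
                        latitude = latitude, longitude = longitude,
                        event_year = NA_integer_, source_id = NA_character_)
  class(out) <- unique(c("occ_tbl", class(out)))
  out
}

# Delimited occurrence fixture with crafted bad rows; returns the path and
# the expected per-reason tallies for an independent recount.
write_occ_fixture <- function(path, n_good = 93) {
  set.seed(99)
  good <- data.frame(
    species = sample(c("Macrocystis pyrifera", "Laminaria digitata"),
                     n_good, replace = TRUE),
    genus = "Genus", order = "Laminariales",
    decimalLatitude = round(runif(n_good, -60, 60), 4),
    decimalLongitude = round(runif(n_good, -179, 179), 4),
    year = sample(1950:2019, n_good, replace = TRUE),
    gbifID = seq_len(n_good)
  )
  bad <- data.frame(
    species = c(rep("Macrocystis pyrifera", 5), "", " "),
    genus = "Genus", order = "Laminariales",
    decimalLatitude = c(95, -91.2, 120, 10, 20, 30, 40),
    decimalLongitude = c(0, 0, 0, 181, -200.5, 50, 60),
    year = 2000, gbifID = 1000 + 1:7
  )
  all <- rbind(good, bad)
  all <- all[sample.int(nrow(all)), ]
  write.csv(all, path, row.names = FALSE, quote = FALSE)
  list(path = path, n_rows = nrow(all), n_good = n_good,
       n_bad_coord = 5, n_blank_species = 2)
}
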