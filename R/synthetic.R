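#' Generate a synthetic environmental layer
#'
#' Builds a layer with a known value field so extraction and envelope code can
#' be tested against ground truth. Three field types:
#' * `"constant"` — every cell holds `value`;
#' * `"gradient"` — a west–east linear ramp: column `c` (1-based) holds
#'   `range[1] + (c-1) * (range[2]-range[1]) / (n_cols-1)`, constant down each
#'   column;
#' * `"random"` — a seeded smooth random field (a sum of low-frequency plane
#'   waves), rescaled onto `range`.
#'
#' A seeded random subset of `floor(land_fraction * n_cells)` cells is set to
#' nodata, emulating land. Same seed, same layer — bit-identical.
#'
#' @param georef A [grid_georef()].
#' @param field `"constant"`, `"gradient"` or `"random"`.
#' @param value Constant value (field `"constant"`).
#' @param range Length-2 numeric range (fields `"gradient"`, `"random"`).
#' @param land_fraction Fraction of cells set to nodata, in \[0, 1\].
#' @param seed Integer seed controlling field and land placement.
#' @param variable_code,units Metadata to record on the layer.
#' @return An [env_layer()].
#' @export
make_synthetic_layer <- function(georef, field = c("constant", "gradient", "random"),
                                 value = 0, range = c(0, 1), land_fraction = 0,
                                 seed = 1, variable_code = "syn_var", units = "") {
  field <- match.arg(field)
  stopifnot(land_fraction >= 0, land_fraction <= 1)
  nr <- georef$n_rows; nc <- georef$n_cols
  withr::with_seed(seed, {
    m <- switch(field,
      constant = matrix(value, nr, nc),
      gradient = {
        ramp <- if (nc == 1) range[1] else
          range[1] + (seq_len(nc) - 1) * (range[2] - range[1]) / (nc - 1)
        matrix(ramp, nr, nc, byrow = TRUE)
      },
      random = {
        x <- (seq_len(nc) - 0.5) / nc
        y <- (seq_len(nr) - 0.5) / nr
        m0 <- matrix(0, nr, nc)
        for (k in 1:6) {
          fx <- stats::runif(1, 0.5, 3); fy <- stats::runif(1, 0.5, 3)
          ph <- stats::runif(2, 0, 2 * pi); amp <- stats::runif(1, 0.3, 1)
          m0 <- m0 + amp * outer(sin(2 * pi * fy * y + ph[1]),
                                 sin(2 * pi * fx * x + ph[2]))
        }
        lo <- min(m0); hi <- max(m0)
        if (hi > lo) range[1] + (m0 - lo) / (hi - lo) * (range[2] - range[1])
        else matrix(mean(range), nr, nc)
      }
    )
    n_land <- floor(land_fraction * nr * nc)
    if (n_land > 0) m[sample.int(nr * nc, n_land)] <- NA_real_
    env_layer(m, georef, variable_code = variable_code, units = units)
  })
}

#' Generate strip ecoregions tiling a grid
#'
#' Partitions the grid's bounding box into `n_regions` equal-width west–east
#' rectangular strips, `eco_id` 1..`n_regions` from west to east. The strips
#' tile the box exactly (no gaps, no overlaps).
#'
#' @param georef A [grid_georef()].
#' @param n_regions Number of strips (>= 1).
#' @return An ecoregion tibble.
#' @export
make_synthetic_ecoregions <- function(georef, n_regions) {
  stopifnot(n_regions >= 1)
  west <- georef$west; east <- georef_east(georef)
  south <- georef_south(georef); north <- georef$north
  w <- (east - west) / n_regions
  geoms <- lapply(seq_len(n_regions), function(i) {
    x0 <- west + (i - 1) * w; x1 <- west + i * w
    list(rbind(c(x0, south), c(x1, south), c(x1, north), c(x0, north),
               c(x0, south)))
  })
  ecoregion_tbl(seq_len(n_regions), paste("Strip", seq_len(n_regions)), geoms)
}

#' Specify a Gaussian species niche
#'
#' The generator's model of the bell-curve niche assumption: a species'
#' occurrence probability at a site is proportional to the product over
#' variables of the Gaussian density of the site's value under that variable's
#' (mean, sd). Independent variables, no covariance.
#'
#' @param species_name Binomial name for the simulated records.
#' @param niche Named list: `variable_code -> c(mean, sd)`, `sd >= 0`.
#' @param n_points Number of records to draw (>= 1).
#' @param seed Integer seed.
#' @param genus,order Taxonomy carried on the records (kelps are order
#'   `"Laminariales"`).
#' @return A `niche_spec` list.
#' @export
niche_spec <- function(species_name, niche, n_points, seed,
                       genus = strsplit(species_name, " ")[[1]][1],
                       order = "Laminariales") {
  stopifnot(n_points >= 1, length(niche) >= 1)
  for (v in niche) stopifnot(length(v) == 2, v[[2]] >= 0)
  structure(list(species_name = species_name, niche = niche,
                 n_points = n_points, seed = as.integer(seed),
                 genus = genus, order = order),
            class = "niche_spec")
}

#' Simulate occurrences from a Gaussian niche
#'
#' Samples `n_points` cells with replacement, with probability proportional to
#' the product over the spec's variables of the Gaussian density of the cell's
#' value; nodata cells have probability zero. Records are placed at cell
#' centers (so extraction recovers exactly the generating cell value);
#' `jitter > 0` instead displaces each point uniformly within the central
#' `jitter` fraction of its cell, for exercising boundary handling.
#'
#' @param spec A [niche_spec()].
#' @param layers List of aligned [env_layer()]s covering the spec's variables.
#' @param jitter In \[0, 1\); 0 (default) places points exactly at centers.
#' @return An occurrence tibble (same columns as [read_occurrences()]).
#' @export
make_synthetic_occurrences <- function(spec, layers, jitter = 0) {
  stopifnot(inherits(spec, "niche_spec"), jitter >= 0, jitter < 1)
  codes <- vapply(layers, function(l) l$variable_code, character(1))
  g <- layers[[1]]$georef
  for (l in layers) {
    if (!same_georef(l$georef, g)) stop("layers must share one grid", call. = FALSE)
  }
  missing_vars <- setdiff(names(spec$niche), codes)
  if (length(missing_vars) > 0) {
    stop("spec variables not covered by layers: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  log_w <- matrix(0, g$n_rows, g$n_cols)
  for (vc in names(spec$niche)) {
    mu <- spec$niche[[vc]][[1]]; sd <- spec$niche[[vc]][[2]]
    v <- layers[[match(vc, codes)]]$values
    lw <- if (sd > 0) stats::dnorm(v, mu, sd, log = TRUE)
          else ifelse(v == mu, 0, -Inf)  # sd -> 0+ limit: exact matches only
    log_w <- log_w + lw
  }
  log_w[is.na(log_w)] <- -Inf
  if (all(log_w == -Inf)) {
    stop("degenerate niche spec: every cell has zero probability", call. = FALSE)
  }
  w <- exp(log_w - max(log_w))
  withr::with_seed(spec$seed, {
    idx <- sample.int(length(w), spec$n_points, replace = TRUE, prob = as.vector(w))
    # w is in matrix (column-major) order: recover (row, col)
    row <- ((idx - 1) %% g$n_rows) + 1
    col <- ((idx - 1) %/% g$n_rows) + 1
    lon <- g$west + (col - 0.5) * g$dx
    lat <- g$north - (row - 0.5) * g$dy
    if (jitter > 0) {
      lon <- lon + stats::runif(length(lon), -0.5, 0.5) * jitter * g$dx
      lat <- lat + stats::runif(length(lat), -0.5, 0.5) * jitter * g$dy
    }
    out <- tibble::tibble(
      species = spec$species_name, genus = spec$genus, order = spec$order,
      latitude = lat, longitude = lon, event_year = NA_integer_,
      source_id = sprintf("sim-%s-%04d", gsub(" ", "_", spec$species_name),
                          seq_len(spec$n_points))
    )
    attr(out, "rejections") <- empty_rejections()
    attr(out, "provenance") <- list(source = "synthetic", accessed = NA_character_)
    class(out) <- unique(c("occ_tbl", class(out)))
    out
  })
}

#' The default synthetic study system
#'
#' A self-contained world for tests and demonstrations: an 80 x 80
#' quarter-degree grid (lon/lat -10..10) with 15% of cells as land (one shared
#' mask across layers), three environmental layers — sea-surface temperature
#' (`bo_sst_x`, a west–east ramp 8–22 °C), salinity (`bo_salinity`, smooth
#' random 31–36 PSS) and nitrate (`bo_nitrate`, smooth random 2–20 µmol/L) —
#' four strip ecoregions, three kelp species with Gaussian niches and skewed
#' sample sizes (1200 / 400 / 80, echoing the strong sampling imbalance of
#' real occurrence archives) plus one non-kelp decoy species (order Fucales)
#' that the taxon filter must remove.
#'
#' @param seed Integer master seed; all sub-generators derive from it.
#' @param n_regions Number of strip ecoregions.
#' @return List with `georef`, `layers` (named list), `regions`, `occurrences`
#'   (all species bound together), and `specs` (the generating niche specs).
#' @export
synthetic_world <- function(seed = 1, n_regions = 4) {
  g <- grid_georef(west = -10, north = 10, dx = 0.25, dy = 0.25,
                   n_rows = 80, n_cols = 80)
  sst <- make_synthetic_layer(g, "gradient", range = c(8, 22), seed = seed + 1,
                              variable_code = "bo_sst_x", units = "°C")
  sal <- make_synthetic_layer(g, "random", range = c(31, 36), seed = seed + 2,
                              variable_code = "bo_salinity", units = "PSS")
  no3 <- make_synthetic_layer(g, "random", range = c(2, 20), seed = seed + 3,
                              variable_code = "bo_nitrate", units = "µmol/L")
  # one shared land mask so every layer agrees on what is ocean
  land <- withr::with_seed(seed + 4,
                           sample.int(g$n_rows * g$n_cols,
                                      floor(0.15 * g$n_rows * g$n_cols)))
  for (nm in c("sst", "sal", "no3")) {
    l <- get(nm); l$values[land] <- NA_real_; assign(nm, l)
  }
  layers <- list(bo_sst_x = sst, bo_salinity = sal, bo_nitrate = no3)

  specs <- list(
    niche_spec("Macrocystis synthetica",
               list(bo_sst_x = c(12, 1.5), bo_salinity = c(33.5, 0.8),
                    bo_nitrate = c(12, 3)),
               n_points = 1200, seed = seed + 11),
    niche_spec("Laminaria ficta",
               list(bo_sst_x = c(16, 2), bo_salinity = c(34, 1),
                    bo_nitrate = c(8, 3)),
               n_points = 400, seed = seed + 12),
    niche_spec("Nereocystis simulata",
               list(bo_sst_x = c(10, 1), bo_salinity = c(33, 0.7),
                    bo_nitrate = c(15, 4)),
               n_points = 80, seed = seed + 13),
    niche_spec("Fucus imaginarius",
               list(bo_sst_x = c(14, 3)),
               n_points = 60, seed = seed + 14, order = "Fucales")
  )
  occs <- dplyr::bind_rows(lapply(specs, make_synthetic_occurrences,
                                  layers = layers))
  attr(occs, "rejections") <- empty_rejections()
  attr(occs, "provenance") <- list(source = "synthetic_world", accessed = NA_character_)
  class(occs) <- unique(c("occ_tbl", class(occs)))

  list(georef = g, layers = layers,
       regions = make_synthetic_ecoregions(g, n_regions),
       occurrences = occs, specs = specs)
}

#' Write a synthetic world to disk in the formats the readers consume
#'
#' Materializes [synthetic_world()] as files — occurrences as CSV, layers as
#' ESRI ASCII grids, ecoregions as GeoJSON — and returns a ready-to-run
#' pipeline configuration pointing at them, guaranteeing round-trip coverage
#' of every reader.
#'
#' @param dir Output directory (created if needed).
#' @param seed Master seed passed to [synthetic_world()].
#' @param ... Passed on to [synthetic_world()].
#' @return A [pipeline_config()] list (invisibly returns file paths as attrs).
#' @export
write_synthetic_world <- function(dir, seed = 1, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- synthetic_world(seed = seed, ...)
  occ_path <- file.path(dir, "occurrences.csv")
  write_occurrences(w$occurrences, occ_path)
  layer_cfg <- purrr::imap(w$layers, function(l, nm) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_env_layer(l, p)
    list(path = p, variable_code = l$variable_code, units = l$units)
  })
  eco_path <- file.path(dir, "ecoregions.geojson")
  write_ecoregions_geojson(w$regions, eco_path)
  pipeline_config(
    occurrences = occ_path,
    layers = unname(layer_cfg),
    ecoregions = eco_path,
    output_dir = file.path(dir, "out"),
    seed = seed
  )
}
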