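#' Build an ecoregion table in memory
#'
#' @param eco_id Integer ids, unique.
#' @param eco_name Region names.
#' @param geometry List of geometries, one per region; each geometry is a list
#'   of rings, each ring an `n x 2` matrix of (longitude, latitude) vertices.
#'   Rings need not be explicitly closed. Point membership uses the even-odd
#'   rule, so interior rings act as holes.
#' @return An ecoregion tibble (`eco_id`, `eco_name`, `geometry`, `repaired`).
#' @export
ecoregion_tbl <- function(eco_id, eco_name, geometry) {
  eco_id <- as.integer(eco_id)
  if (anyDuplicated(eco_id)) stop("eco_id values must be unique", call. = FALSE)
  stopifnot(length(eco_id) == length(eco_name), length(eco_id) == length(geometry))
  geometry <- lapply(geometry, function(geom) {
    lapply(geom, function(ring) {
      ring <- as.matrix(ring)
      stopifnot(ncol(ring) == 2, nrow(ring) >= 3)
      unname(ring)
    })
  })
  tibble::tibble(
    eco_id = eco_id, eco_name = as.character(eco_name),
    geometry = geometry,
    repaired = vapply(geometry, function(g) any(vapply(g, ring_self_intersects, logical(1))),
                      logical(1))
  )
}

#' Load ecoregion polygons from GeoJSON
#'
#' Reads a Marine-Ecoregions-of-the-World-style FeatureCollection (Polygon or
#' MultiPolygon features, WGS84). Self-intersecting rings are flagged in the
#' `repaired` column and a message is emitted; membership tests use the
#' even-odd rule, which resolves a self-crossing ring the same way a zero-width
#' buffer repair would for point-in-polygon purposes.
#'
#' @param path GeoJSON file.
#' @param id_field,name_field Property names holding the integer id and the
#'   region name. Defaults try the package's own schema then the MEOW one.
#' @return An ecoregion tibble; duplicate ids raise an error.
#' @export
load_ecoregions <- function(path, id_field = c("eco_id", "ECO_CODE"),
                            name_field = c("eco_name", "ECOREGION")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  if (length(feats) == 0) stop("no features in ", path, call. = FALSE)

  props <- feats[[1]]$properties
  pick_field <- function(cands, what) {
    hit <- cands[cands %in% names(props)]
    if (length(hit) == 0) {
      stop("no ", what, " field (tried: ", paste(cands, collapse = ", "),
           ") in GeoJSON properties", call. = FALSE)
    }
    hit[[1]]
  }
  idf <- pick_field(id_field, "id")
  nmf <- pick_field(name_field, "name")

  ring_mat <- function(coords) {
    do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
  }
  geoms <- lapply(feats, function(f) {
    geom <- f$geometry
    if (geom$type == "Polygon") {
      lapply(geom$coordinates, ring_mat)
    } else if (geom$type == "MultiPolygon") {
      unlist(lapply(geom$coordinates, function(poly) lapply(poly, ring_mat)),
             recursive = FALSE)
    } else {
      stop("unsupported geometry type: ", geom$type, call. = FALSE)
    }
  })
  ids <- vapply(feats, function(f) as.integer(f$properties[[idf]]), integer(1))
  nms <- vapply(feats, function(f) as.character(f$properties[[nmf]]), character(1))
  out <- ecoregion_tbl(ids, nms, geoms)
  if (any(out$repaired)) {
    message(sum(out$repaired), " ecoregion(s) had self-intersecting rings; ",
            "flagged `repaired`, membership uses even-odd interpretation")
  }
  out
}

#' Write ecoregions as GeoJSON
#' @param regions An ecoregion tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ecoregions_geojson <- function(regions, path) {
  feats <- purrr::pmap(regions[c("eco_id", "eco_name", "geometry")],
    function(eco_id, eco_name, geometry) {
      rings <- lapply(geometry, function(r) {
        r <- close_ring(r)
        lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
      })
      list(type = "Feature",
           properties = list(eco_id = eco_id, eco_name = eco_name),
           geometry = list(type = "Polygon", coordinates = rings))
    })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

close_ring <- function(ring) {
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring
}

# Proper-intersection scan over non-adjacent segment pairs (O(n^2); region
# polygons here are small). Touching endpoints are not flagged.
ring_self_intersects <- function(ring) {
  r <- close_ring(ring)
  n <- nrow(r) - 1
  if (n < 4) return(FALSE)
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- cross2(p4 - p3, p1 - p3); d2 <- cross2(p4 - p3, p2 - p3)
    d3 <- cross2(p2 - p1, p3 - p1); d4 <- cross2(p2 - p1, p4 - p1)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 2, n)) {
      if (i == 1 && j == n) next  # adjacent through closure
      if (seg_int(r[i, ], r[i + 1, ], r[j, ], r[j + 1, ])) return(TRUE)
    }
  }
  FALSE
}

cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

# Rings of one region as a single NA-separated boundary matrix for mgcv::in.out.
region_boundary <- function(geometry) {
  parts <- lapply(geometry, close_ring)
  sep <- matrix(NA_real_, 1, 2)
  do.call(rbind, Reduce(function(a, b) c(a, list(sep), list(b)),
                        parts[-1], list(parts[[1]])))
}

# TRUE where point i lies on the boundary of the geometry (within eps degrees).
on_boundary <- function(geometry, lon, lat, eps = 1e-9) {
  out <- rep(FALSE, length(lon))
  for (ring in geometry) {
    r <- close_ring(ring)
    for (i in seq_len(nrow(r) - 1)) {
      a <- r[i, ]; b <- r[i + 1, ]
      ab <- b - a
      len2 <- sum(ab^2)
      if (len2 == 0) next
      t <- ((lon - a[1]) * ab[1] + (lat - a[2]) * ab[2]) / len2
      t <- pmin(1, pmax(0, t))
      d2 <- (lon - (a[1] + t * ab[1]))^2 + (lat - (a[2] + t * ab[2]))^2
      out <- out | (d2 <= eps^2)
    }
  }
  out
}

# Planar distance (degrees) from each point to the nearest boundary segment.
dist_to_region <- function(geometry, lon, lat) {
  best <- rep(Inf, length(lon))
  for (ring in geometry) {
    r <- close_ring(ring)
    for (i in seq_len(nrow(r) - 1)) {
      a <- r[i, ]; b <- r[i + 1, ]
      ab <- b - a
      len2 <- sum(ab^2)
      t <- if (len2 == 0) rep(0, length(lon)) else
        pmin(1, pmax(0, ((lon - a[1]) * ab[1] + (lat - a[2]) * ab[2]) / len2))
      d2 <- (lon - (a[1] + t * ab[1]))^2 + (lat - (a[2] + t * ab[2]))^2
      best <- pmin(best, sqrt(d2))
    }
  }
  best
}

#' Assign occurrences to ecoregions
#'
#' Each record gets the `eco_id` of the region containing it (even-odd rule).
#' A point on a boundary shared by two regions goes to the smaller `eco_id` —
#' deterministic and order-independent. Points inside no region are snapped to
#' the nearest region within `snap_tolerance` degrees (planar distance to the
#' boundary) when that tolerance is positive; otherwise they stay unassigned
#' (`eco_id` `NA`) and are logged with reason `"unassigned_no_ecoregion"`.
#' Unassigned records are retained in the output (downstream summaries skip
#' them), so `assigned + unassigned = total`.
#'
#' @param occs An occurrence tibble.
#' @param regions An ecoregion tibble ([load_ecoregions()], [ecoregion_tbl()]).
#' @param snap_tolerance Snap distance in degrees; default 0 (strict
#'   containment). Occurrence coordinates occasionally sit just outside
#'   coastal polygons, which is what a small positive tolerance is for.
#' @return The occurrence tibble with `eco_id` and `eco_name` columns added.
#' @export
assign_ecoregions <- function(occs, regions, snap_tolerance = 0) {
  stopifnot(nrow(regions) > 0)
  regions <- dplyr::arrange(regions, .data$eco_id)
  n <- nrow(occs)
  lon <- normalize_lon(occs$longitude)
  lat <- occs$latitude
  eco_id <- rep(NA_integer_, n)
  pts <- cbind(lon, lat)

  for (i in seq_len(nrow(regions))) {
    open <- is.na(eco_id)
    if (!any(open)) break
    geom <- regions$geometry[[i]]
    inside <- mgcv::in.out(region_boundary(geom), pts[open, , drop = FALSE])
    inside <- inside | on_boundary(geom, lon[open], lat[open])
    eco_id[which(open)[inside]] <- regions$eco_id[[i]]
  }

  if (snap_tolerance > 0 && any(is.na(eco_id))) {
    open <- which(is.na(eco_id))
    d <- sapply(seq_len(nrow(regions)), function(i) {
      dist_to_region(regions$geometry[[i]], lon[open], lat[open])
    })
    d <- matrix(d, nrow = length(open))
    # nearest region within tolerance; ties go to the smaller eco_id because
    # regions are scanned in ascending-id order and ties keep the first min
    best <- apply(d, 1, which.min)
    best_d <- d[cbind(seq_along(open), best)]
    hit <- best_d <= snap_tolerance
    eco_id[open[hit]] <- regions$eco_id[best[hit]]
  }

  out <- occs
  out$eco_id <- eco_id
  out$eco_name <- regions$eco_name[match(eco_id, regions$eco_id)]
  out <- keep_occ_attrs(out, occs)
  if (any(is.na(eco_id))) {
    out <- append_rejections(out, tibble::tibble(
      row_number = which(is.na(eco_id)),
      reason_code = "unassigned_no_ecoregion",
      raw_line = paste(occs$species[is.na(eco_id)], lat[is.na(eco_id)],
                       lon[is.na(eco_id)], sep = ",")
    ))
  }
  out
}
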