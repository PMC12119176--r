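test_that("ASCII grid write/read round trip is exact", {
  g <- grid_georef(west = -3.5, north = 2.25, dx = 0.25, dy = 0.25,
                   n_rows = 2, n_cols = 2)
  vals <- matrix(c(1.25, -2.5, NA, 4.875), 2, 2, byrow = TRUE)
  l <- env_layer(vals, g, "bo_sst_x", "°C")
  p <- withr::local_tempfile(fileext = ".asc")
  write_env_layer(l, p)
  l2 <- read_env_layer(p, "bo_sst_x", "°C")
  expect_identical(l2$values, l$values)
  expect_equal(l2$georef, l$georef)
  expect_equal(l2$units, "°C")

  # full-precision doubles survive the round trip too
  set.seed(3)
  l3 <- random_layer(7, 5, west = 10, north = 20, dx = 0.1, dy = 0.1,
                     na_frac = 0.2)
  write_env_layer(l3, p)
  expect_identical(read_env_layer(p, "test_var")$values, l3$values)
})

test_that("malformed grid files raise format errors", {
  p <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "cellsize 1", "1 2", "3 4"), p)
  expect_error(read_env_layer(p, "x"), "header")  # no origin -> not georeferenced
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "1 2 3 4 5 6 7 8"), p)
  expect_error(read_env_layer(p, "x"), "multi-band|truncated")
  expect_error(read_env_layer("nope.asc", "x"), "not found")
  p_tif <- withr::local_tempfile(fileext = ".tif")
  file.create(p_tif)
  expect_error(read_env_layer(p_tif, "x"), "GeoTIFF")
})

test_that("point extraction agrees with the exhaustive containment oracle", {
  set.seed(11)
  for (rep in 1:6) {
    l <- random_layer(sample(1:50, 1), sample(1:50, 1), na_frac = 0.1)
    g <- l$georef
    n <- 200
    # mix of interior, boundary-ish and outside points
    lon <- runif(n, g$west - 2 * g$dx, georef_east(g) + 2 * g$dx)
    lat <- runif(n, georef_south(g) - 2 * g$dy, g$north + 2 * g$dy)
    edge_lon <- g$west + sample(0:g$n_cols, 20, replace = TRUE) * g$dx
    edge_lat <- g$north - sample(0:g$n_rows, 20, replace = TRUE) * g$dy
    lon <- c(lon, edge_lon); lat <- c(lat, edge_lat)
    got <- extract_at_points(l, data.frame(latitude = lat, longitude = lon))
    expect_identical(got, oracle_extract(l, lat, lon))
  }
})

test_that("extraction honours the half-open convention and bounds", {
  g <- grid_georef(0, 2, 1, 1, 2, 2)
  l <- env_layer(matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE), g, "v")
  pt <- function(lat, lon) extract_at_points(l, data.frame(latitude = lat, longitude = lon))
  expect_equal(pt(1.5, 0.5), 1)   # exact center of cell (1,1)
  expect_equal(pt(2, 0), 1)       # north-west corner belongs to cell (1,1)
  expect_equal(pt(1, 1), 4)       # interior shared corner -> south-east cell
  expect_true(is.na(pt(1.5, -1e-9)))  # just west of the grid
  expect_true(is.na(pt(0, 0.5)))      # south edge is open
  expect_equal(pt(1.5, 1), 2)     # shared vertical edge -> eastern cell
})

test_that("extraction is translation-consistent", {
  set.seed(21)
  l <- random_layer(15, 12, west = -30, north = 10, dx = 0.5, dy = 0.25)
  n <- 300
  lon <- runif(n, l$georef$west, georef_east(l$georef))
  lat <- runif(n, georef_south(l$georef), l$georef$north)
  base <- extract_at_points(l, data.frame(latitude = lat, longitude = lon))
  for (shift in list(c(5, -3), c(-12.5, 7.25))) {
    g2 <- grid_georef(l$georef$west + shift[1], l$georef$north + shift[2],
                      l$georef$dx, l$georef$dy, l$georef$n_rows, l$georef$n_cols)
    l2 <- env_layer(l$values, g2, l$variable_code)
    got <- extract_at_points(l2, data.frame(latitude = lat + shift[2],
                                            longitude = lon + shift[1]))
    expect_identical(got, base)
  }
})

test_that("longitude 180 is treated as -180 before lookup", {
  g <- grid_georef(-180, 1, 1, 1, 1, 360)
  l <- env_layer(matrix(seq_len(360), 1), g, "v")
  expect_equal(extract_at_points(l, data.frame(latitude = 0.5, longitude = 180)),
               1)  # wraps to the -180 cell
  expect_equal(extract_at_points(l, data.frame(latitude = 0.5, longitude = -180)),
               1)
})

test_that("land removal keeps ocean points, logs land points, is idempotent", {
  g <- grid_georef(0, 10, 1, 1, 10, 10)
  m <- matrix(1, 10, 10)
  m[, 6:10] <- NA  # eastern half is land
  ref <- env_layer(m, g, "ocean_ref")
  set.seed(5)
  ocean <- occ_fixture("Kelp sp.", runif(50, 0.01, 9.99), runif(50, 0.01, 4.99))
  land <- occ_fixture("Kelp sp.", runif(50, 0.01, 9.99), runif(50, 5.01, 9.99))
  occ <- dplyr::bind_rows(ocean, land)
  class(occ) <- unique(c("occ_tbl", class(occ)))

  kept <- drop_land_points(occ, ref)
  expect_equal(nrow(kept), 50)
  expect_true(all(kept$longitude < 5))
  rej <- rejections(kept)
  expect_equal(nrow(rej), 50)
  expect_true(all(rej$reason_code == "land_or_out_of_domain"))

  again <- drop_land_points(kept, ref)
  expect_equal(tibble::as_tibble(again), tibble::as_tibble(kept))

  all_land <- drop_land_points(keep_occ_attrs(land, land), ref)
  expect_equal(nrow(all_land), 0)
  expect_equal(nrow(rejections(all_land)), 50)
})
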