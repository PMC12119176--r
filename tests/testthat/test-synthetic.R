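test_that("synthetic layers realize the requested field and are seed-deterministic", {
  g <- grid_georef(0, 1, 1, 1, 1, 11)
  const <- make_synthetic_layer(g, "constant", value = 12)
  expect_true(all(const$values == 12))

  grad <- make_synthetic_layer(g, "gradient", range = c(0, 10))
  expect_equal(as.vector(grad$values), 0:10)  # column c holds (c-1) * 1.0

  g2 <- grid_georef(0, 10, 0.5, 0.5, 20, 20)
  r1 <- make_synthetic_layer(g2, "random", range = c(3, 9), seed = 7,
                             land_fraction = 0.2)
  r2 <- make_synthetic_layer(g2, "random", range = c(3, 9), seed = 7,
                             land_fraction = 0.2)
  expect_identical(r1$values, r2$values)
  expect_equal(sum(is.na(r1$values)), floor(0.2 * 400))
  expect_true(all(r1$values >= 3 & r1$values <= 9, na.rm = TRUE))
  r3 <- make_synthetic_layer(g2, "random", range = c(3, 9), seed = 8)
  expect_false(identical(r1$values, r3$values))
})

test_that("strip ecoregions tile the bounding box exactly", {
  g <- grid_georef(-10, 10, 0.5, 0.5, 40, 40)
  one <- make_synthetic_ecoregions(g, 1)
  expect_equal(oracle_ring_area(one$geometry[[1]][[1]]), 20 * 20)

  for (n in c(2, 4, 7)) {
    reg <- make_synthetic_ecoregions(g, n)
    areas <- vapply(reg$geometry, function(geo) oracle_ring_area(geo[[1]]),
                    numeric(1))
    expect_equal(sum(areas), 20 * 20)           # union covers the box
    expect_equal(areas, rep(20 * 20 / n, n))    # equal-width strips
    # adjacent strips share only a boundary: x-extents meet exactly
    x_ranges <- t(vapply(reg$geometry, function(geo) range(geo[[1]][, 1]),
                         numeric(2)))
    expect_equal(x_ranges[-1, 1], x_ranges[-n, 2])
  }
  # 4 strips on a 40-column grid: boundaries every 10 columns of longitude
  reg4 <- make_synthetic_ecoregions(g, 4)
  expect_equal(vapply(reg4$geometry, function(geo) min(geo[[1]][, 1]), numeric(1)),
               c(-10, -5, 0, 5))
})

test_that("uniform-layer sampling reduces to uniform over ocean cells", {
  g <- grid_georef(0, 5, 1, 1, 5, 5)
  flat <- make_synthetic_layer(g, "constant", value = 15, land_fraction = 0.2,
                               seed = 3, variable_code = "bo_sst_x")
  n_ocean <- sum(!is.na(flat$values))
  n <- 10000
  spec <- niche_spec("Uniformis aequalis", list(bo_sst_x = c(15, 2)),
                     n_points = n, seed = 5)
  occ <- make_synthetic_occurrences(spec, list(flat))
  expect_equal(nrow(occ), n)
  # no point on land
  expect_true(all(!is.na(extract_at_points(flat, occ))))
  # empirical cell frequencies within 4 sigma of the multinomial expectation
  cell <- paste(occ$latitude, occ$longitude)
  counts <- table(cell)
  expect_equal(length(counts), n_ocean)  # every ocean cell hit at n = 10000
  p <- 1 / n_ocean
  tol <- 4 * sqrt(n * p * (1 - p))
  expect_true(all(abs(counts - n * p) <= tol))
})

test_that("occurrence sampling is seed-deterministic and respects sigma -> 0", {
  g <- grid_georef(0, 1, 1, 1, 1, 11)
  grad <- make_synthetic_layer(g, "gradient", range = c(0, 10),
                               variable_code = "v")
  spec0 <- niche_spec("Pointis massa", list(v = c(7, 0)), n_points = 50, seed = 2)
  occ <- make_synthetic_occurrences(spec0, list(grad))
  expect_true(all(extract_at_points(grad, occ) == 7))  # only the mu cell

  spec <- niche_spec("Pointis massa", list(v = c(5, 1)), n_points = 200, seed = 9)
  a <- make_synthetic_occurrences(spec, list(grad))
  b <- make_synthetic_occurrences(spec, list(grad))
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))

  # an unreachable niche is a degenerate-spec error
  bad <- niche_spec("Nullus ubique", list(v = c(99, 0)), n_points = 5, seed = 1)
  expect_error(make_synthetic_occurrences(bad, list(grad)), "degenerate")

  # jittered points stay inside their source cell
  jit <- make_synthetic_occurrences(spec, list(grad), jitter = 0.9)
  expect_identical(extract_at_points(grad, jit),
                   extract_at_points(grad, make_synthetic_occurrences(spec, list(grad))))
})

test_that("gaussian niche sampling recovers the stated mean on a gradient world", {
  g <- grid_georef(0, 1, 0.01, 1, 1, 3001)
  grad <- make_synthetic_layer(g, "gradient", range = c(0, 30),
                               variable_code = "bo_sst_x")
  spec <- niche_spec("Media recta", list(bo_sst_x = c(15, 2)),
                     n_points = 5000, seed = 17)
  occ <- make_synthetic_occurrences(spec, list(grad))
  v <- extract_at_points(grad, occ)
  se <- 2 / sqrt(5000)
  expect_lt(abs(mean(v) - 15), 3 * se)
})

test_that("full pipeline recovers region-restricted generating quartiles", {
  # one ecoregion strip, dense value coverage: the envelope's p25/p75 must sit
  # near the generating Gaussian's quartiles mu -/+ 0.6745 sigma
  g <- grid_georef(0, 1, 0.01, 1, 1, 3001)
  grad <- make_synthetic_layer(g, "gradient", range = c(0, 30),
                               variable_code = "bo_sst_x", units = "°C")
  n <- 5000
  spec <- niche_spec("Media recta", list(bo_sst_x = c(15, 2)),
                     n_points = n, seed = 23)
  occ <- make_synthetic_occurrences(spec, list(grad))
  occ <- assign_ecoregions(occ, make_synthetic_ecoregions(g, 1))
  rows <- summarize_niche(extract_env_table(occ, list(grad)))
  expect_equal(nrow(rows), 1)

  q_se <- function(p) sqrt(p * (1 - p) / n) / stats::dnorm(stats::qnorm(p)) * 2
  expect_lt(abs(rows$p25 - (15 - 0.6745 * 2)), 3 * q_se(0.25))
  expect_lt(abs(rows$p75 - (15 + 0.6745 * 2)), 3 * q_se(0.75))
  expect_lt(abs(rows$mean - 15), 3 * 2 / sqrt(n))
})
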