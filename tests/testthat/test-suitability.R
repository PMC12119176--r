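summary_row <- function(min = 5, p25 = 10, mean = 15, p75 = 20, max = 30,
                        code = "bo_sst_x") {
  tibble::tibble(species = "Kelp sp.", eco_id = 1L, eco_name = "A",
                 variable_code = code, units = "°C", n_obs = 50L,
                 min = min, p25 = p25, mean = mean, p75 = p75, max = max)
}

test_that("recipes derive from envelopes per mode", {
  row <- summary_row()
  iqr <- recipe_from_summary(row, mode = "iqr")
  expect_equal(unlist(iqr[c("lo", "hi", "exclusion_min", "exclusion_max")]),
               c(lo = 10, hi = 20, exclusion_min = 5, exclusion_max = 30))
  rng <- recipe_from_summary(row, mode = "range")
  expect_equal(c(rng$lo, rng$hi), c(5, 30))
  expect_true(is.na(rng$exclusion_min))
  expect_error(recipe_from_summary(row, mode = "bogus"), "mode")

  deg <- recipe_from_summary(summary_row(p25 = 12, p75 = 12), mode = "iqr")
  expect_equal(c(deg$lo, deg$hi), c(12, 12))
})

test_that("band reclassification is inclusive at both ends and nodata-aware", {
  g <- grid_georef(0, 1, 1, 1, 1, 5)
  l <- env_layer(matrix(c(9.99, 10, 15, 20, 20.01), 1), g, "bo_sst_x")
  rec <- band_recipe("bo_sst_x", 10, 20)
  out <- reclassify_band(l, rec)
  expect_equal(as.vector(out$values), c(0, 1, 1, 1, 0))

  # degenerate band holds exactly its single value
  l12 <- env_layer(matrix(c(11.999, 12, 12.001), 1), grid_georef(0, 1, 1, 1, 1, 3),
                   "bo_sst_x")
  expect_equal(as.vector(reclassify_band(l12, band_recipe("bo_sst_x", 12, 12))$values),
               c(0, 1, 0))

  all_na <- env_layer(matrix(NA_real_, 1, 5), g, "bo_sst_x")
  expect_true(all(is.na(reclassify_band(all_na, rec)$values)))

  expect_error(reclassify_band(l, band_recipe("bo_salinity", 10, 20)),
               "bo_salinity")
})

test_that("graded mode scores 2/1/0 through band and exclusion envelope", {
  g <- grid_georef(0, 1, 1, 1, 1, 5)
  l <- env_layer(matrix(c(4, 7, 15, 25, 31), 1), g, "bo_sst_x")
  rec <- recipe_from_summary(summary_row(), mode = "iqr")
  out <- reclassify_band(l, rec, graded = TRUE)
  expect_equal(as.vector(out$values), c(0, 1, 2, 1, 0))
  expect_error(reclassify_band(l, recipe_from_summary(summary_row(), mode = "range"),
                               graded = TRUE), "exclusion")
})

test_that("reclassify + weighted stack equals per-cell brute force", {
  set.seed(41)
  g <- grid_georef(-5, 5, 0.25, 0.25, 40, 40)
  layers <- lapply(1:4, function(i) {
    m <- matrix(rnorm(1600, mean = 15, sd = 5), 40, 40)
    m[sample.int(1600, 60)] <- NA
    env_layer(m, g, paste0("v", i))
  })
  recs <- lapply(1:4, function(i) {
    lo <- runif(1, 8, 14)
    band_recipe(paste0("v", i), lo, lo + runif(1, 1, 8))
  })
  w <- c(2, 0, 1, 3)
  bins <- Map(reclassify_band, layers, recs)
  smap <- stack_score(bins, weights = w)

  brute <- matrix(NA_real_, 40, 40)
  for (r in 1:40) for (c in 1:40) {
    s <- 0; ok <- TRUE
    for (i in 1:4) {
      v <- layers[[i]]$values[r, c]
      if (is.na(v)) { ok <- FALSE; break }
      s <- s + w[i] * as.numeric(v >= recs[[i]]$lo & v <= recs[[i]]$hi)
    }
    if (ok) brute[r, c] <- s
  }
  expect_identical(smap$scores, brute)
  # score bounds and integrality (integer weights)
  sc <- smap$scores[!is.na(smap$scores)]
  expect_true(all(sc >= 0 & sc <= sum(w)))
  expect_true(all(sc == round(sc)))
  expect_equal(smap$max_score, sum(w))

  # order invariance: permuting layer/weight pairs leaves the map unchanged
  perm <- c(3, 1, 4, 2)
  smap2 <- stack_score(bins[perm], weights = w[perm])
  expect_identical(smap2$scores, smap$scores)

  # zero-weight neutrality (nodata-free layer): drop it and its weight
  ones <- env_layer(matrix(1, 40, 40), g, "ones")
  sA <- stack_score(c(bins[c(1, 3, 4)], list(ones)), weights = c(2, 1, 3, 0))
  sB <- stack_score(bins[c(1, 3, 4)], weights = c(2, 1, 3))
  expect_identical(sA$scores, sB$scores)
})

test_that("widening a band never decreases any cell's score", {
  set.seed(43)
  g <- grid_georef(0, 4, 0.5, 0.5, 8, 8)
  l <- env_layer(matrix(runif(64, 0, 30), 8, 8), g, "v")
  narrow <- reclassify_band(l, band_recipe("v", 12, 16))
  wide <- reclassify_band(l, band_recipe("v", 10, 20))
  s1 <- stack_score(list(narrow), weights = 2)
  s2 <- stack_score(list(wide), weights = 2)
  expect_true(all(s2$scores >= s1$scores, na.rm = TRUE))
})

test_that("layers on coarser grids are resampled by nearest cell", {
  fine <- grid_georef(0, 4, 0.5, 0.5, 8, 8)
  coarse <- grid_georef(0, 4, 2, 2, 2, 2)
  cl <- env_layer(matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE), coarse, "c")
  fl <- env_layer(matrix(1, 8, 8), fine, "f")
  smap <- stack_score(list(fl, cl), weights = c(1, 1))
  expect_equal(smap$georef, fine)  # finest grid wins by default
  # each fine cell inherits the coarse cell containing its center
  expect_equal(smap$scores[1, 1], 2)  # NW: coarse 1 + fine 1
  expect_equal(smap$scores[1, 8], 1)  # NE: coarse 0 + fine 1
  expect_equal(smap$scores[8, 1], 1)
  expect_equal(smap$scores[8, 8], 2)
  expect_error(stack_score(list(), numeric(0)), "no layers")
})

test_that("lenient stacking rescales by the available weight", {
  g <- grid_georef(0, 1, 1, 1, 1, 2)
  a <- env_layer(matrix(c(1, 1), 1), g, "a")
  b <- env_layer(matrix(c(1, NA), 1), g, "b")
  strict <- stack_score(list(a, b), weights = c(1, 1))
  expect_equal(as.vector(strict$scores), c(2, NA))
  lenient <- stack_score(list(a, b), weights = c(1, 1), na_policy = "lenient")
  expect_equal(as.vector(lenient$scores), c(2, 2))  # 1 * (2/1) where b missing
})

test_that("zonal statistics match a cell-center membership scan", {
  set.seed(47)
  g <- grid_georef(0, 10, 0.5, 0.5, 20, 20)
  scores <- matrix(sample(0:3, 400, replace = TRUE), 20, 20)
  scores[sample.int(400, 30)] <- NA
  smap <- structure(list(georef = g, scores = scores, recipes = "v",
                         weights = 3, max_score = 3),
                    class = "suitability_map")
  zones <- make_synthetic_ecoregions(g, 2)
  zs <- zonal_stats(smap, zones)

  centers <- cell_centers(g)
  centers$score <- as.vector(t(scores))
  for (z in zones$eco_id) {
    member <- vapply(seq_len(nrow(centers)), function(i) {
      for (j in sort(zones$eco_id)) {
        if (oracle_in_geometry(zones$geometry[[which(zones$eco_id == j)]],
                               centers$longitude[i], centers$latitude[i]))
          return(j)
      }
      NA_integer_
    }, integer(1))
    v <- centers$score[!is.na(member) & member == z]
    v <- v[!is.na(v)]
    row <- zs[zs$zone_id == z, ]
    expect_equal(row$n_cells, length(v))
    expect_equal(row$mean_score, mean(v))
    expect_equal(row$max_score_observed, max(v))
    expect_equal(row$fraction_at_max, mean(v == 3))
  }
  expect_equal(zs$mean_score, sort(zs$mean_score, decreasing = TRUE))

  # a zone entirely outside the grid reports zero cells
  far <- ecoregion_tbl(9L, "Far", list(list(rbind(c(100, 0), c(101, 0),
                                                  c(101, 1), c(100, 1),
                                                  c(100, 0)))))
  zs2 <- zonal_stats(smap, far)
  expect_equal(zs2$n_cells, 0L)
  expect_true(is.na(zs2$mean_score))

  # uniform map, one zone covering the grid
  uni <- structure(list(georef = g, scores = matrix(2, 20, 20), recipes = "v",
                        weights = 3, max_score = 3), class = "suitability_map")
  zsu <- zonal_stats(uni, make_synthetic_ecoregions(g, 1))
  expect_equal(zsu$mean_score, 2)
  expect_equal(zsu$fraction_at_max, 0)  # max attainable is 3
})
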