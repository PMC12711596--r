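test_that("landscape spec validation rejects degenerate worlds", {
  expect_error(landscape_spec(extent = c(0, 10)), "positive")
  expect_error(landscape_spec(cell_size = -1), "positive")
  expect_error(landscape_spec(extent = c(10, 7), cell_size = 3), "multiple")
  expect_error(landscape_spec(collinear_pairs = list(c(1, 2, 1))), "in \\[0, 1\\)")
  expect_error(landscape_spec(collinear_pairs = list(c(1, 1, 0.5))),
               "indices")
})

test_that("generated stacks are standardised, collinearity-controlled and deterministic", {
  spec <- landscape_spec(extent = c(100, 100), cell_size = 1,
                         n_predictors = 4,
                         collinear_pairs = list(c(1, 2, 0.95), c(3, 4, 0)),
                         smoothness = 2, seed = 11)
  st <- make_stack(spec)
  expect_length(st$layers, 4)
  for (l in st$layers) {
    expect_equal(mean(l$values), 0, tolerance = 1e-10)
    expect_equal(sd(as.vector(l$values)), 1, tolerance = 1e-10)
  }
  # requested correlations reproduced (sample-correlation oracle)
  v <- lapply(st$layers, function(l) as.vector(l$values))
  expect_equal(cor(v[[1]], v[[2]]), 0.95, tolerance = 1e-10)
  expect_lt(abs(cor(v[[3]], v[[4]])), 0.05)
  # same spec, same seed: bit-identical
  st2 <- make_stack(spec)
  expect_identical(st$layers[[2]]$values, st2$layers[[2]]$values)
  # different seed: different fields
  st3 <- make_stack(landscape_spec(extent = c(100, 100), cell_size = 1,
                                   n_predictors = 4, smoothness = 2,
                                   seed = 12))
  expect_false(identical(st$layers[[1]]$values, st3$layers[[1]]$values))
})

test_that("true suitability surface is the inverse-logit of the linear predictor", {
  st <- toy_stack(3, 15, seed = 2)
  # all-zero coefficients: uniform 0.5
  t0 <- make_truth(st, c(env_1 = 0), intercept = 0)
  expect_true(all(t0$surface$values == 0.5))
  # huge intercept: saturates at 1
  t1 <- make_truth(st, c(env_1 = 0), intercept = 50)
  expect_true(all(t1$surface$values > 0.999999))
  # cell-wise recomputation oracle on a random landscape
  cf <- c(env_1 = 1.3, env_3 = -0.7)
  tt <- make_truth(st, cf, intercept = 0.2)
  z <- function(nm) {
    v <- st$layers[[nm]]$values
    (v - mean(v)) / sd(as.vector(v))
  }
  manual <- plogis(0.2 + 1.3 * z("env_1") - 0.7 * z("env_3"))
  expect_equal(tt$surface$values, manual, tolerance = 1e-12)
  # single unit coefficient on a standardised layer: median near 0.5
  tm <- make_truth(st, c(env_2 = 1))
  expect_equal(median(tm$surface$values), 0.5, tolerance = 0.05)
  expect_error(make_truth(st, c(not_a_layer = 1)), "unknown layer")
})

test_that("presence sampling follows the product-probability law", {
  # step-function truth: all samples in the truth = 1 cells
  v <- matrix(0, 20, 20); v[, 11:20] <- 1
  tr <- list(surface = raster_grid(v))
  class(tr) <- "true_suitability"
  ones <- const_raster(1, 20)
  p1 <- sample_presences(tr, ones, 200, seed = 3)
  expect_true(all(p1$lon > 10))
  # step-function bias with uniform truth: all samples in bias = 1 cells
  tru <- list(surface = const_raster(1, 20)); class(tru) <- "true_suitability"
  bias <- raster_grid(v)
  p2 <- sample_presences(tru, bias, 200, seed = 4)
  expect_true(all(p2$lon > 10))
  # two equal blocks {0.5, 1}: expected share in the high block is 2/3
  bv <- matrix(0.5, 20, 20); bv[, 11:20] <- 1
  p3 <- sample_presences(tru, raster_grid(bv), 3000, seed = 5)
  share <- mean(p3$lon > 10)
  expect_lt(abs(share - 2 / 3), 3 * sqrt(2 / 9 / 3000))  # 3-sigma binomial
  # chi-squared goodness of fit on a 4-block landscape, n = 1e4
  tv <- matrix(0.2, 20, 20)
  tv[1:10, 1:10] <- 0.4; tv[11:20, 1:10] <- 0.8; tv[1:10, 11:20] <- 0.6
  tr4 <- list(surface = raster_grid(tv)); class(tr4) <- "true_suitability"
  p4 <- sample_presences(tr4, ones, 10000, seed = 6)
  block <- paste(p4$lon > 10, p4$lat > 10)
  # table() orders blocks FALSE/FALSE, FALSE/TRUE, TRUE/FALSE, TRUE/TRUE
  probs <- c(0.4, 0.8, 0.6, 0.2)
  obs <- as.vector(table(block))
  pval <- chisq.test(obs, p = probs / sum(probs))$p.value
  expect_gt(pval, 0.01)
  # all-zero product surface errors
  z0 <- list(surface = const_raster(0, 5)); class(z0) <- "true_suitability"
  expect_error(sample_presences(z0, const_raster(1, 5), 10), "all zero")
})

test_that("target-group pooling keeps species labels and counts", {
  st <- toy_stack(2, 12, seed = 7)
  tr <- make_truth(st, c(env_1 = 1))
  b <- const_raster(1, 12)
  tg <- make_target_group(list(tr), b, n_species = 5, n_per_species = 30,
                          seed = 8)
  expect_equal(nrow(tg), 5 * 30)
  expect_length(unique(tg$species), 5)
})

test_that("future stacks apply deltas and GCM noise as specified", {
  st <- toy_stack(2, 10, seed = 9)
  # zero deltas, zero noise: identical to current
  f0 <- make_futures(st, list(base = c(env_1 = 0)), n_gcms = 2,
                     gcm_noise_sd = 0, seed = 1)
  expect_equal(f0$base[[1]]$layers$env_1$values, st$layers$env_1$values)
  expect_equal(f0$base[[2]]$layers$env_2$values, st$layers$env_2$values)
  # delta +1, zero noise: per-cell difference exactly 1
  f1 <- make_futures(st, list(warm = c(env_1 = 1)), n_gcms = 1,
                     gcm_noise_sd = 0, seed = 1)
  expect_equal(f1$warm[[1]]$layers$env_1$values - st$layers$env_1$values,
               matrix(1, 10, 10))
  expect_equal(f1$warm[[1]]$layers$env_2$values, st$layers$env_2$values)
  expect_error(make_futures(st, list(bad = c(nope = 1))), "unknown layer")
  expect_error(make_futures(st, list(a = c(env_1 = 0)), n_gcms = 0), ">= 1")
})

test_that("zone partitions tile the extent exactly", {
  # single zone: the full rectangle
  z1 <- make_zones(c(50, 30), 1, seed = 2)
  expect_equal(ensdm:::polygon_area(z1$polygons[[1]]), 1500)
  # many zones: areas sum to the extent area
  z <- make_zones(c(100, 80), 7, seed = 3)
  areas <- vapply(z$polygons, ensdm:::polygon_area, numeric(1))
  expect_equal(sum(areas), 100 * 80, tolerance = 1e-6)
  expect_true(all(areas > 0))
  expect_error(make_zones(c(0, 10), 2), "invalid")
})

test_that("wind farm generator honours capacities and status distribution", {
  wf <- make_windfarms(c(100, 100), 25, capacity_range_mw = c(50, 60),
                       status_probs = c(0, 0, 1), seed = 4)
  expect_true(all(wf$capacity_mw >= 50 & wf$capacity_mw <= 60))
  expect_true(all(wf$status == "proposed"))
  expect_true(all(wf$x >= 0 & wf$x <= 100 & wf$y >= 0 & wf$y <= 100))
  expect_error(make_windfarms(c(100, 100), 5, capacity_range_mw = c(-1, 10)),
               "positive")
})

test_that("geojson round trips preserve zones and wind farms", {
  z <- make_zones(c(40, 40), 3, seed = 5)
  pz <- tempfile(fileext = ".geojson")
  write_zones_geojson(z, pz)
  z2 <- read_zones_geojson(pz)
  expect_equal(z2$labels, z$labels)
  expect_equal(vapply(z2$polygons, ensdm:::polygon_area, numeric(1)),
               vapply(z$polygons, ensdm:::polygon_area, numeric(1)),
               tolerance = 1e-6)
  wf <- make_windfarms(c(40, 40), 4, seed = 6)
  pw <- tempfile(fileext = ".geojson")
  write_windfarms_geojson(wf, pw)
  wf2 <- read_windfarms_geojson(pw)
  expect_equal(wf2$capacity_mw, wf$capacity_mw, tolerance = 1e-8)
  expect_equal(wf2$status, wf$status)
})
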