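test_that("envelope index matches its definition cell-wise", {
  st <- toy_stack(2, 20, seed = 41)
  set.seed(42)
  pres <- data.frame(lon = runif(30, 0, 20), lat = runif(30, 0, 20))
  idx <- envelope_index(st, pres)
  # direct formula oracle
  pv <- extract_stack(st, pres$lon, pres$lat)
  manual <- -(abs((st$layers$env_1$values - mean(pv$env_1)) / sd(pv$env_1)) +
              abs((st$layers$env_2$values - mean(pv$env_2)) / sd(pv$env_2))) / 2
  expect_equal(idx$surface$values, manual, tolerance = 1e-12)
  # maximum attainable is 0 at the presence centroid
  expect_lte(max(idx$surface$values), 0)
  # a synthetic cell 2 sd away on one layer and at the mean on the other
  # scores exactly -1: evaluate via the formula components
  z1 <- (mean(pv$env_1) + 2 * sd(pv$env_1) - mean(pv$env_1)) / sd(pv$env_1)
  expect_equal(-(abs(z1) + 0) / 2, -1)
  # scale invariance: rescaling a layer leaves the index unchanged
  st2 <- st
  st2$layers$env_1$values <- 100 + 7 * st$layers$env_1$values
  idx2 <- envelope_index(st2, pres)
  expect_equal(idx2$surface$values, idx$surface$values, tolerance = 1e-10)
})

test_that("median split uses presence index values with >= going high", {
  surf <- raster_grid(matrix(seq(-3, 0, length.out = 25), 5, 5))
  idx <- structure(list(surface = surf), class = "envelope_index")
  # presences picked so their index values are close to {-2, -1, 0}
  ctr <- grid_centers(surf)
  v <- as.vector(surf$values)
  pick <- c(which.min(abs(v + 2)), which.min(abs(v + 1)), which.max(v))
  pres <- data.frame(lon = ctr$x[pick], lat = ctr$y[pick])
  z <- split_zones(idx, pres)
  t <- attr(z, "threshold")
  expect_equal(t, sort(v[pick])[2])  # median of three
  # direct comparison oracle
  expect_equal(z$values, ifelse(surf$values >= t, 1, 0))
  # all-identical presence index: low zone is the strictly-below set
  pres2 <- data.frame(lon = rep(ctr$x[10], 3), lat = rep(ctr$y[10], 3))
  z2 <- split_zones(idx, pres2)
  expect_equal(sum(z2$values == 0), sum(v < v[10]))
})

test_that("survey effort rasterises counts and smooths with a focal mean", {
  tmpl <- const_raster(0, 9)
  # 9 records in one interior cell -> 3x3 block of ones after smoothing
  tg <- data.frame(lon = rep(4.5, 9), lat = rep(4.5, 9))
  eff <- survey_effort(tg, tmpl, window = 3)
  expect_equal(eff$surface$values[4:6, 4:6], matrix(1, 3, 3))
  expect_equal(eff$max_effort, 1)
  expect_equal(sum(eff$surface$values > 0), 9)
  # constant field unchanged by the focal mean
  set.seed(5)
  xy <- expand.grid(x = (1:9) - 0.5, y = (1:9) - 0.5)
  tg2 <- data.frame(lon = xy$x, lat = xy$y)
  eff2 <- survey_effort(tg2, tmpl, window = 3)
  expect_equal(eff2$surface$values, matrix(1, 9, 9))
  expect_error(survey_effort(tg[0, ], tmpl), "empty")
})

test_that("pseudo-absence sampling honours zone, effort floor and weights", {
  nr <- 40
  # low zone: left half; effort: gradient with known maximum
  zones <- raster_grid(cbind(matrix(0, nr, nr / 2), matrix(1, nr, nr / 2)))
  ev <- matrix(rep(seq(1, 10, length.out = nr), each = nr), nr)
  eff <- structure(list(surface = raster_grid(ev), max_effort = 10),
                   class = "survey_effort")
  pres <- data.frame(lon = runif(20, 0, 5), lat = runif(20, 0, 40))
  pa <- sample_pseudo_absences(zones, eff, pres, n = 100,
                               effort_floor = 0.40, replicates = 3, seed = 9)
  pa0 <- pa[pa$label == 0, ]
  expect_equal(nrow(pa0), 300)
  expect_equal(unname(table(pa0$replicate_id)), rep(100L, 3),
               ignore_attr = TRUE)
  # no PA in the high zone
  expect_true(all(extract_values(zones, pa0$x, pa0$y) == 0))
  # none below the 40% effort floor (max_effort 10 -> effort >= 4)
  expect_true(all(extract_values(eff$surface, pa0$x, pa0$y) >= 4))
  expect_equal(attr(pa, "floor_used"), 0.40)
  # no PA shares a cell with a presence
  pres_cells <- paste(cell_of(zones, pres$lon, pres$lat)[, 1],
                      cell_of(zones, pres$lon, pres$lat)[, 2])
  pa_cells <- paste(cell_of(zones, pa0$x, pa0$y)[, 1],
                    cell_of(zones, pa0$x, pa0$y)[, 2])
  expect_length(intersect(pres_cells, pa_cells), 0)
  # equal summed weights per replicate
  for (r in 1:3) {
    sub <- pa[pa$replicate_id == r, ]
    expect_equal(sum(sub$weight[sub$label == 1]),
                 sum(sub$weight[sub$label == 0]))
  }
  # determinism and replicate independence
  pa2 <- sample_pseudo_absences(zones, eff, pres, n = 100,
                                effort_floor = 0.40, replicates = 3,
                                seed = 9)
  expect_identical(as.data.frame(pa), as.data.frame(pa2))
  r1 <- pa0[pa0$replicate_id == 1, c("x", "y")]
  r2 <- pa0[pa0$replicate_id == 2, c("x", "y")]
  expect_false(identical(r1$x, r2$x))
})

test_that("floor relaxation is monotone and bottoms out in degraded mode", {
  nr <- 10
  zones <- const_raster(0, nr)  # everything low zone
  ev <- matrix(rep(seq(0, 10, length.out = nr), each = nr), nr)
  eff <- structure(list(surface = raster_grid(ev), max_effort = 10),
                   class = "survey_effort")
  pres <- data.frame(lon = 0.5, lat = 0.5)
  # candidates(floor1) subset of candidates(floor2) when floor1 >= floor2
  n_at <- function(fl) {
    pa <- suppressWarnings(
      sample_pseudo_absences(zones, eff, pres, n = 1, effort_floor = fl,
                             relax_step = 1, replicates = 1, seed = 1))
    attr(pa, "n_candidates")
  }
  cands <- vapply(c(0.8, 0.5, 0.2, 0), n_at, numeric(1))
  expect_true(all(diff(cands) >= 0))
  # requesting more PAs than cells forces relaxation to 0 and a degraded flag
  expect_warning(
    paD <- sample_pseudo_absences(zones, eff, pres, n = 500,
                                  effort_floor = 0.4, replicates = 1,
                                  seed = 2),
    "with replacement")
  expect_true(attr(paD, "degraded"))
  expect_equal(attr(paD, "floor_used"), 0)
  expect_equal(sum(paD$label == 0), 500)
  # exhaustive case: exactly n candidates -> all selected, any seed
  zx <- const_raster(0, 4)  # 16 cells
  effu <- structure(list(surface = const_raster(1, 4), max_effort = 1),
                    class = "survey_effort")
  presx <- data.frame(lon = 0.5, lat = 0.5)  # occupies 1 cell -> 15 left
  paA <- sample_pseudo_absences(zx, effu, presx, n = 15, effort_floor = 0,
                                replicates = 1, seed = 10)
  paB <- sample_pseudo_absences(zx, effu, presx, n = 15, effort_floor = 0,
                                replicates = 1, seed = 999)
  a <- paA[paA$label == 0, c("x", "y")]
  b <- paB[paB$label == 0, c("x", "y")]
  expect_equal(a[order(a$x, a$y), ], b[order(b$x, b$y), ],
               ignore_attr = TRUE)
  expect_error(sample_pseudo_absences(const_raster(1, 4), effu, presx,
                                      n = 5, seed = 1), "empty")
})

test_that("PA cells are uniform over the low zone under uniform effort", {
  # 4-block landscape, uniform effort, 1e4 draws
  nr <- 200  # 40,000 cells, half low zone
  zv <- matrix(1, nr, nr); zv[, 1:(nr / 2)] <- 0
  zones <- raster_grid(zv)
  effu <- structure(list(surface = const_raster(1, nr), max_effort = 1),
                    class = "survey_effort")
  pres <- data.frame(lon = numeric(0), lat = numeric(0))
  pa <- sample_pseudo_absences(zones, effu, pres, n = 10000,
                               effort_floor = 0.4, replicates = 1, seed = 3)
  pa0 <- pa[pa$label == 0, ]
  # four equal blocks of the low zone (left half split in x and y)
  block <- paste(pa0$x > nr / 4, pa0$y > nr / 2)
  obs <- as.vector(table(block))
  pval <- chisq.test(obs, p = rep(0.25, 4))$p.value
  expect_gt(pval, 0.01)
})
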