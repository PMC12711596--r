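#' Named, co-registered collection of raster layers
#'
#' @param layers named list of `raster_grid` objects sharing shape, origin and
#'   cell size. The union of the members' nodata masks is applied to every
#'   layer so masks are identical.
#' @return an object of class `predictor_stack`.
#' @export
predictor_stack <- function(layers) {
  if (length(layers) < 1L) stop("need at least one layer")
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("layers must have unique non-empty names")
  if (!all(vapply(layers, inherits, TRUE, "raster_grid")))
    stop("every layer must be a raster_grid")
  tpl <- layers[[1]]
  for (l in layers) if (!same_grid(tpl, l))
    stop("all layers must share shape, origin and cell size")
  bad <- Reduce(`|`, lapply(layers, function(l) !is.finite(l$values)))
  layers <- lapply(layers, function(l) {
    l$values[bad] <- NA_real_
    l
  })
  structure(list(layers = layers), class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  tpl <- x$layers[[1]]
  cat(sprintf("<predictor_stack> %d layers, %d x %d cells (%.4g km)\n",
              length(x$layers), nrow(tpl$values), ncol(tpl$values),
              tpl$cellsize))
  cat("  ", paste(names(x$layers), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
names.predictor_stack <- function(x) names(x$layers)

#' @export
`[.predictor_stack` <- function(x, i) predictor_stack(x$layers[i])

#' Cell values of every layer as a matrix
#' @param stack a `predictor_stack`.
#' @return numeric matrix, cells (storage order) x layers.
#' @export
stack_values <- function(stack) {
  vapply(stack$layers, function(l) as.vector(l$values),
         numeric(length(stack$layers[[1]]$values)))
}

#' Extract layer values at planar points
#' @param stack a `predictor_stack`.
#' @param x,y point coordinates (km).
#' @return data.frame, one column per layer.
#' @export
extract_stack <- function(stack, x, y) {
  as.data.frame(lapply(stack$layers, extract_values, x = x, y = y))
}

#' Resample layers onto a template grid
#'
#' Continuous layers are interpolated bilinearly; categorical layers take the
#' nearest source cell. Template cells whose (bilinear or nearest) support
#' falls outside the source extent become nodata, and the union of the
#' resampled layers' nodata masks is applied by [predictor_stack()].
#'
#' @param layers named list of `raster_grid` objects (any grids).
#' @param template `raster_grid` defining the target grid.
#' @param types character vector, `"continuous"` (default) or `"categorical"`,
#'   recycled along layers.
#' @return a `predictor_stack` on the template grid.
#' @export
align_layers <- function(layers, template, types = "continuous") {
  types <- rep_len(types, length(layers))
  ctr <- grid_centers(template)
  out <- vector("list", length(layers))
  for (k in seq_along(layers)) {
    src <- layers[[k]]
    v <- if (types[k] == "categorical")
      resample_nearest(src, ctr$x, ctr$y)
    else resample_bilinear(src, ctr$x, ctr$y)
    if (all(is.na(v))) stop("layer '", names(layers)[k],
                            "' does not overlap the template extent")
    out[[k]] <- raster_grid(matrix(v, nrow(template$values)),
                            template$xmin, template$ymin, template$cellsize)
  }
  names(out) <- names(layers)
  predictor_stack(out)
}

resample_nearest <- function(src, x, y) extract_values(src, x, y)

resample_bilinear <- function(src, x, y) {
  v <- src$values
  nr <- nrow(v); nc <- ncol(v); cs <- src$cellsize
  # fractional position in units of cell centres
  fc <- (x - src$xmin) / cs - 0.5
  fr <- (y - src$ymin) / cs - 0.5
  c0 <- pmin(pmax(floor(fc), 0), nc - 1); c1 <- pmin(c0 + 1, nc - 1)
  r0 <- pmin(pmax(floor(fr), 0), nr - 1); r1 <- pmin(r0 + 1, nr - 1)
  inside <- fc >= -0.5 & fc <= nc - 0.5 & fr >= -0.5 & fr <= nr - 0.5
  wc <- pmin(pmax(fc - c0, 0), 1); wr <- pmin(pmax(fr - r0, 0), 1)
  g <- function(r, c) v[cbind(r + 1, c + 1)]
  out <- (1 - wr) * ((1 - wc) * g(r0, c0) + wc * g(r0, c1)) +
    wr * ((1 - wc) * g(r1, c0) + wc * g(r1, c1))
  out[!inside] <- NA_real_
  out
}

#' Slope and aspect from a digital elevation model
#'
#' Horn's 3x3 finite-difference method on a planar DEM whose horizontal and
#' vertical units agree (or are reconciled via `z_factor`). Slope is returned
#' in degrees; aspect in compass degrees `[0, 360)` (0 = north, clockwise),
#' with flat cells set to the sentinel `-1`. Border cells (no full 3x3
#' neighbourhood) are nodata.
#'
#' @param dem a `raster_grid` of elevations.
#' @param z_factor multiplier converting elevation units to km (default 1).
#' @return list with `raster_grid` elements `slope` and `aspect`.
#' @export
terrain_slope_aspect <- function(dem, z_factor = 1) {
  v <- dem$values * z_factor
  nr <- nrow(v); nc <- ncol(v); cs <- dem$cellsize
  if (nr < 3 || nc < 3)
    stop("DEM must be at least 3 x 3 cells for slope/aspect")
  slope <- matrix(NA_real_, nr, nc); aspect <- matrix(NA_real_, nr, nc)
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  # neighbours: row + 1 is north (y increases with row)
  a <- v[i + 1, j - 1]; b <- v[i + 1, j]; cc <- v[i + 1, j + 1]
  d <- v[i, j - 1];                        f <- v[i, j + 1]
  g <- v[i - 1, j - 1]; h <- v[i - 1, j]; k <- v[i - 1, j + 1]
  dzdx <- ((cc + 2 * f + k) - (a + 2 * d + g)) / (8 * cs)
  dzdy <- ((a + 2 * b + cc) - (g + 2 * h + k)) / (8 * cs)
  slope[i, j] <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  asp <- (atan2(dzdx, dzdy) * 180 / pi + 180) %% 360  # downslope bearing
  flat <- dzdx == 0 & dzdy == 0
  asp[flat] <- -1
  aspect[i, j] <- asp
  list(slope = raster_grid(slope, dem$xmin, dem$ymin, cs),
       aspect = raster_grid(aspect, dem$xmin, dem$ymin, cs))
}

#' Euclidean distance to the nearest feature
#'
#' Every cell holds the planar distance (km) from its centre to the nearest
#' feature. Point features are `(x, y)` rows; polygon features contribute
#' their vertices and cells inside a polygon get distance 0.
#'
#' @param features data.frame with columns `x`, `y` (points), or a list of
#'   polygon vertex matrices (closed rings, columns x and y).
#' @param template `raster_grid` defining the output grid.
#' @return a `raster_grid` of distances (km).
#' @export
distance_raster <- function(features, template) {
  ctr <- grid_centers(template)
  if (is.data.frame(features)) {
    if (nrow(features) == 0L) stop("empty feature set")
    px <- features$x; py <- features$y
    d <- nearest_dist(ctr$x, ctr$y, px, py)
  } else if (is.list(features)) {
    if (length(features) == 0L) stop("empty feature set")
    px <- unlist(lapply(features, function(p) p[, 1]))
    py <- unlist(lapply(features, function(p) p[, 2]))
    d <- nearest_dist(ctr$x, ctr$y, px, py)
    inside <- rep(FALSE, nrow(ctr))
    for (p in features) inside <- inside | point_in_polygon(ctr$x, ctr$y, p)
    d[inside] <- 0
  } else stop("'features' must be a data.frame of points or list of polygons")
  raster_grid(matrix(d, nrow(template$values)),
              template$xmin, template$ymin, template$cellsize)
}

# min distance from each (x, y) to the feature points, chunked to bound memory
nearest_dist <- function(x, y, px, py) {
  n <- length(x); d <- numeric(n)
  chunk <- max(1L, floor(2e6 / length(px)))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    dx <- outer(x[s:e], px, "-"); dy <- outer(y[s:e], py, "-")
    d[s:e] <- sqrt(.rowMins(dx * dx + dy * dy))
  }
  d
}

.rowMins <- function(m) do.call(pmin, as.data.frame(m))

# even-odd ray casting; points on an edge are resolved arbitrarily
point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}

#' Iterative variance-inflation-factor screening
#'
#' For each layer j, VIF_j = 1 / (1 - R^2_j) from the linear regression of
#' layer j on all other layers over a seeded subsample of valid cells. While
#' any VIF is at or above `threshold`, the layer with the largest VIF is
#' dropped (perfectly collinear layers count as infinite and go first; ties
#' drop the lexicographically later name) and VIFs are recomputed.
#'
#' @param stack a `predictor_stack` with at least two layers.
#' @param sample_cells number of valid cells to sample (default 10000; all
#'   valid cells if fewer).
#' @param threshold VIF threshold (default 5): retained layers all have
#'   VIF < threshold.
#' @param seed integer seed for the cell subsample.
#' @return list with `stack` (reduced `predictor_stack`) and `report`, a list
#'   with `steps` (data.frame `dropped`, `vif`) and `retained`
#'   (data.frame `layer`, `vif`).
#' @export
vif_screen <- function(stack, sample_cells = 10000, threshold = 5, seed = 1) {
  X <- stack_values(stack)
  if (ncol(X) < 2L) stop("need at least two layers for VIF screening")
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]
  set.seed(seed)
  if (nrow(X) > sample_cells)
    X <- X[sample.int(nrow(X), sample_cells), , drop = FALSE]
  keep <- colnames(X)
  steps <- data.frame(dropped = character(0), vif = numeric(0))
  repeat {
    vifs <- vif_values(X[, keep, drop = FALSE])
    worst <- max(vifs)
    if (worst < threshold || length(keep) == 1L) break
    cand <- names(vifs)[vifs == worst]
    drop <- sort(cand, decreasing = TRUE)[1]
    steps <- rbind(steps, data.frame(dropped = drop, vif = unname(vifs[drop])))
    keep <- setdiff(keep, drop)
  }
  vifs <- vif_values(X[, keep, drop = FALSE])
  list(stack = stack[keep],
       report = list(steps = steps,
                     retained = data.frame(layer = keep, vif = unname(vifs))))
}

vif_values <- function(X) {
  p <- ncol(X)
  if (p == 1L) return(stats::setNames(1, colnames(X)))
  out <- numeric(p)
  for (j in seq_len(p)) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- if (tss == 0) 1 else 1 - rss / tss
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  stats::setNames(out, colnames(X))
}

#' Cell-wise mean of several predictor stacks
#'
#' The multi-model (GCM) ensemble average: stacks must share layer names and
#' grid; the mean is arithmetic per cell and layer, nodata where any member
#' is nodata.
#'
#' @param stacks list of `predictor_stack` objects.
#' @return a `predictor_stack`.
#' @export
gcm_mean <- function(stacks) {
  if (length(stacks) < 1L) stop("need at least one stack")
  nm <- names(stacks[[1]]$layers)
  for (s in stacks) {
    if (!setequal(names(s$layers), nm))
      stop("all stacks must share layer names")
    if (!same_grid(s$layers[[1]], stacks[[1]]$layers[[1]]))
      stop("all stacks must share the grid")
  }
  tpl <- stacks[[1]]$layers[[1]]
  out <- lapply(nm, function(l) {
    m <- Reduce(`+`, lapply(stacks, function(s) s$layers[[l]]$values)) /
      length(stacks)
    raster_grid(m, tpl$xmin, tpl$ymin, tpl$cellsize)
  })
  names(out) <- nm
  predictor_stack(out)
}

#' Fraction of a category within aggregation blocks
#'
#' Helper for proportion-cover layers: aggregates a fine categorical raster
#' into `factor` x `factor` blocks, each coarse cell holding the fraction of
#' its fine cells equal to `category`.
#'
#' @param categorical a `raster_grid` of integer class codes.
#' @param category the class code of interest.
#' @param factor integer block size (fine cells per coarse cell side).
#' @return a `raster_grid` at the coarser resolution.
#' @export
fraction_cover <- function(categorical, category, factor) {
  v <- categorical$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr %% factor != 0 || nc %% factor != 0)
    stop("raster dimensions must be multiples of 'factor'")
  hit <- (v == category) * 1
  rows <- (seq_len(nr) - 1) %/% factor
  cols <- (seq_len(nc) - 1) %/% factor
  agg <- rowsum(t(rowsum(hit, rows)), cols) / factor^2
  raster_grid(t(agg), categorical$xmin, categorical$ymin,
              categorical$cellsize * factor)
}
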