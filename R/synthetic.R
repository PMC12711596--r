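#' Specification of a synthetic landscape
#'
#' Defines a planar study area (km units, origin at (0, 0)) and the
#' statistical structure of its predictor layers: number of layers, spatial
#' smoothness, and engineered collinearity between named pairs.
#'
#' @param extent numeric length-2, width and height of the landscape in km;
#'   both must be positive integer multiples of `cell_size`.
#' @param cell_size cell side length in km.
#' @param n_predictors number of predictor layers.
#' @param collinear_pairs list of numeric triples `(i, j, rho)`: layer `j` is
#'   rebuilt as `rho * layer_i + sqrt(1 - rho^2) * noise` so the sample
#'   correlation between layers `i` and `j` equals `rho` (indices 1-based,
#'   `0 <= rho < 1`).
#' @param smoothness Gaussian smoothing radius in cells (0 = white noise).
#' @param seed integer; fully determines the generated landscape.
#' @return an object of class `landscape_spec`.
#' @export
landscape_spec <- function(extent = c(100, 100), cell_size = 1,
                           n_predictors = 5, collinear_pairs = list(),
                           smoothness = 2, seed = 1) {
  if (length(extent) != 2 || any(!is.finite(extent)) || any(extent <= 0))
    stop("invalid landscape spec: 'extent' must be two positive numbers")
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("invalid landscape spec: 'cell_size' must be positive")
  k <- extent / cell_size
  if (any(abs(k - round(k)) > 1e-9))
    stop("invalid landscape spec: extent must be a multiple of cell_size")
  for (p in collinear_pairs) {
    if (length(p) != 3) stop("collinear pair must be (i, j, rho)")
    if (p[3] < 0 || p[3] >= 1) stop("pair correlation must be in [0, 1)")
    if (any(p[1:2] < 1 | p[1:2] > n_predictors) || p[1] == p[2])
      stop("collinear pair indices out of range")
  }
  structure(list(extent = extent, cell_size = cell_size,
                 n_predictors = n_predictors,
                 collinear_pairs = collinear_pairs,
                 smoothness = smoothness, seed = as.integer(seed)),
            class = "landscape_spec")
}

# smoothed standardised Gaussian random field on an nr x nc grid
random_field <- function(nr, nc, smoothness) {
  m <- matrix(stats::rnorm(nr * nc), nr, nc)
  m <- gaussian_blur(m, smoothness)
  (m - mean(m)) / stats::sd(m)
}

#' Generate a synthetic predictor stack
#'
#' Each layer is a smoothed Gaussian random field standardised to mean 0 and
#' sd 1 over the landscape. Collinear pairs are imposed exactly: the target
#' layer's field is first residualised against the source layer, then mixed
#' as `rho * source + sqrt(1 - rho^2) * residual`, so the empirical
#' correlation equals the requested `rho` to machine precision.
#'
#' @param spec a [landscape_spec()].
#' @return a `predictor_stack` with layers `env_1 ... env_n`.
#' @export
make_stack <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  nr <- as.integer(round(spec$extent[2] / spec$cell_size))
  nc <- as.integer(round(spec$extent[1] / spec$cell_size))
  set.seed(spec$seed)
  fields <- replicate(spec$n_predictors,
                      random_field(nr, nc, spec$smoothness),
                      simplify = FALSE)
  for (p in spec$collinear_pairs) {
    i <- p[1]; j <- p[2]; rho <- p[3]
    a <- as.vector(fields[[i]]); b <- as.vector(fields[[j]])
    resid <- b - a * sum(a * b) / sum(a * a)   # empirically orthogonal part
    resid <- (resid - mean(resid)) / stats::sd(resid)
    mix <- rho * a + sqrt(1 - rho^2) * resid
    mix <- (mix - mean(mix)) / stats::sd(mix)
    fields[[j]] <- matrix(mix, nr, nc)
  }
  layers <- lapply(fields, raster_grid, xmin = 0, ymin = 0,
                   cellsize = spec$cell_size)
  names(layers) <- paste0("env_", seq_len(spec$n_predictors))
  predictor_stack(layers)
}

#' Known true suitability surface
#'
#' Builds the ground-truth habitat suitability as an inverse-logit linear
#' model of the (standardised) predictor layers:
#' `surface = plogis(intercept + sum_j coef_j * z_j)`. Used to test
#' parameter/surface recovery of the modelling pipeline.
#'
#' @param stack a `predictor_stack`.
#' @param coefficients named numeric vector; names must be stack layers.
#' @param intercept scalar intercept on the logit scale.
#' @param seed accepted for interface symmetry; the surface is deterministic
#'   given the stack and coefficients.
#' @return object of class `true_suitability`: list with `coefficients`,
#'   `intercept` and `surface` (a `raster_grid` in `[0, 1]`).
#' @export
make_truth <- function(stack, coefficients, intercept = 0, seed = NULL) {
  unknown <- setdiff(names(coefficients), names(stack$layers))
  if (length(unknown))
    stop("unknown layer name(s): ", paste(unknown, collapse = ", "))
  tpl <- stack$layers[[1]]
  eta <- matrix(intercept, nrow(tpl$values), ncol(tpl$values))
  for (nm in names(coefficients)) {
    v <- stack$layers[[nm]]$values
    mu <- mean(v, na.rm = TRUE); sdv <- stats::sd(as.vector(v), na.rm = TRUE)
    z <- if (sdv > 0) (v - mu) / sdv else v * 0
    eta <- eta + coefficients[[nm]] * z
  }
  surf <- stats::plogis(eta)
  surf[!is.finite(tpl$values)] <- NA_real_
  structure(list(coefficients = coefficients, intercept = intercept,
                 surface = raster_grid(surf, tpl$xmin, tpl$ymin,
                                       tpl$cellsize)),
            class = "true_suitability")
}

#' Observer-accessibility bias field
#'
#' A relative survey-accessibility surface in `[0, 1]` (max exactly 1),
#' emulating higher observer density near accessible areas. Built as a
#' smoothed random field mapped through the logistic function and rescaled.
#'
#' @param template `raster_grid` giving the grid.
#' @param smoothness Gaussian radius in cells.
#' @param strength logit-scale spread; 0 gives a uniform field.
#' @param seed integer seed.
#' @return a `raster_grid` with values in `[0, 1]`, maximum 1.
#' @export
make_bias_field <- function(template, smoothness = 5, strength = 2, seed = 1) {
  set.seed(seed)
  f <- random_field(nrow(template$values), ncol(template$values), smoothness)
  b <- stats::plogis(strength * f)
  b <- b / max(b)
  b[!is.finite(template$values)] <- NA_real_
  raster_grid(b, template$xmin, template$ymin, template$cellsize)
}

#' Sample presence records from a true suitability surface
#'
#' Cells are drawn with replacement with probability proportional to
#' `truth$surface * bias`, emulating occurrence records collected under an
#' accessibility-biased survey effort. Record coordinates are cell centres.
#'
#' @param truth a `true_suitability`.
#' @param bias a `raster_grid` bias field co-registered with the truth
#'   surface (use a constant-1 raster for unbiased sampling).
#' @param n_target number of records to draw.
#' @param seed integer seed.
#' @param species species label for the records.
#' @return occurrence data.frame with columns `id`, `species`, `lon`, `lat`,
#'   `date`, `basis_of_record` (planar km in `lon`/`lat`).
#' @export
sample_presences <- function(truth, bias, n_target, seed = 1,
                             species = "virtual_species") {
  surf <- truth$surface
  if (!same_grid(surf, bias)) stop("truth and bias are not co-registered")
  p <- as.vector(surf$values) * as.vector(bias$values)
  p[!is.finite(p)] <- 0
  if (sum(p) <= 0) stop("cannot sample: product surface is all zero")
  set.seed(seed)
  idx <- sample.int(length(p), n_target, replace = TRUE, prob = p)
  ctr <- grid_centers(surf)
  data.frame(id = paste0(species, "_", seq_len(n_target)),
             species = species,
             lon = ctr$x[idx], lat = ctr$y[idx],
             date = "2000-01-01",
             basis_of_record = "HumanObservation",
             stringsAsFactors = FALSE)
}

#' Pooled occurrences of surrogate (target-group) species
#'
#' Samples `n_species` surrogate species under the SAME bias field (their
#' own suitability surfaces may differ), pooling the records. The pooled
#' table drives the survey-effort layer used for pseudo-absence bias
#' correction; the default of 19 species mirrors a typical target-group set
#' of similarly detectable birds.
#'
#' @param truth_list list of `true_suitability` objects, recycled over
#'   species.
#' @param bias a `raster_grid` bias field.
#' @param n_species number of surrogate species (>= 1).
#' @param n_per_species records per species.
#' @param seed integer seed.
#' @return occurrence data.frame (see [sample_presences()]), `species`
#'   labelling the surrogate.
#' @export
make_target_group <- function(truth_list, bias, n_species = 19,
                              n_per_species = 200, seed = 1) {
  if (n_species < 1) stop("n_species must be >= 1")
  if (!is.list(truth_list) || inherits(truth_list, "true_suitability"))
    truth_list <- list(truth_list)
  out <- vector("list", n_species)
  for (s in seq_len(n_species)) {
    tr <- truth_list[[(s - 1) %% length(truth_list) + 1]]
    out[[s]] <- sample_presences(tr, bias, n_per_species,
                                 seed = seed + s,
                                 species = sprintf("surrogate_%02d", s))
  }
  do.call(rbind, out)
}

#' Perturbed future predictor stacks from pseudo-GCMs
#'
#' For each scenario, each of `n_gcms` pseudo global circulation models
#' shifts the named layers by the scenario's delta plus a GCM-specific
#' smooth noise field of sd `gcm_noise_sd`, emulating between-model spread.
#'
#' @param stack current `predictor_stack`.
#' @param scenario_deltas named list: scenario -> named numeric vector of
#'   per-layer shifts (layers not named are unshifted).
#' @param n_gcms number of pseudo-GCMs per scenario (default 5).
#' @param gcm_noise_sd sd of the per-GCM smooth noise (0 = none).
#' @param seed integer seed.
#' @param smoothness Gaussian radius (cells) of the GCM noise fields.
#' @return named list: scenario -> list of `predictor_stack` (one per GCM).
#' @export
make_futures <- function(stack, scenario_deltas, n_gcms = 5,
                         gcm_noise_sd = 0.1, seed = 1, smoothness = 5) {
  if (n_gcms < 1) stop("n_gcms must be >= 1")
  lapply(stats::setNames(nm = names(scenario_deltas)), function(sc) {
    deltas <- scenario_deltas[[sc]]
    unknown <- setdiff(names(deltas), names(stack$layers))
    if (length(unknown))
      stop("delta for unknown layer(s): ", paste(unknown, collapse = ", "))
    lapply(seq_len(n_gcms), function(g) {
      set.seed(seed + 1000L * match(sc, names(scenario_deltas)) + g)
      layers <- lapply(stats::setNames(nm = names(stack$layers)), function(nm) {
        l <- stack$layers[[nm]]
        v <- l$values
        if (nm %in% names(deltas)) v <- v + deltas[[nm]]
        if (gcm_noise_sd > 0)
          v <- v + gcm_noise_sd *
            random_field(nrow(v), ncol(v), smoothness)
        raster_grid(v, l$xmin, l$ymin, l$cellsize)
      })
      predictor_stack(layers)
    })
  })
}

#' Voronoi zone partition of a rectangular extent
#'
#' `n_zones` seed points drawn uniformly in the extent; each zone is the
#' Voronoi cell of its seed clipped to the extent rectangle, so the polygons
#' tile the extent exactly (no gaps, no overlaps).
#'
#' @param extent numeric length-2 (width, height) in km, origin (0, 0).
#' @param n_zones number of zones (>= 1).
#' @param seed integer seed.
#' @return object of class `zone_set`: list with `labels`, `seeds`
#'   (data.frame x, y) and `polygons` (list of vertex matrices).
#' @export
make_zones <- function(extent, n_zones = 4, seed = 1) {
  if (length(extent) != 2 || any(!is.finite(extent)) || any(extent <= 0))
    stop("invalid extent")
  if (n_zones < 1) stop("n_zones must be >= 1")
  W <- extent[1]; H <- extent[2]
  set.seed(seed)
  sx <- stats::runif(n_zones, 0, W); sy <- stats::runif(n_zones, 0, H)
  rect <- cbind(c(0, W, W, 0), c(0, 0, H, H))
  polys <- lapply(seq_len(n_zones), function(i) {
    poly <- rect
    for (j in seq_len(n_zones)[-i]) {
      # keep the half-plane closer to seed i than to seed j
      a <- 2 * (sx[j] - sx[i]); b <- 2 * (sy[j] - sy[i])
      cc <- sx[j]^2 + sy[j]^2 - sx[i]^2 - sy[i]^2
      poly <- clip_halfplane(poly, a, b, cc)
      if (nrow(poly) == 0) break
    }
    poly
  })
  structure(list(labels = paste0("zone_", seq_len(n_zones)),
                 seeds = data.frame(x = sx, y = sy),
                 polygons = polys),
            class = "zone_set")
}

# Sutherland-Hodgman clip of a convex polygon to {a x + b y <= c}
clip_halfplane <- function(poly, a, b, c) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  out <- matrix(numeric(0), 0, 2)
  f <- a * poly[, 1] + b * poly[, 2] - c
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    if (f[k] <= 0) out <- rbind(out, poly[k, ])
    if ((f[k] > 0) != (f[k2] > 0)) {
      t <- f[k] / (f[k] - f[k2])
      out <- rbind(out, poly[k, ] + t * (poly[k2, ] - poly[k, ]))
    }
  }
  out
}

# shoelace polygon area
polygon_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])) / 2
}

#' Synthetic wind-farm point table
#'
#' Uniform random farm locations with capacities (MW) and development
#' statuses drawn from the given distribution.
#'
#' @param extent numeric length-2 (width, height) in km.
#' @param n_farms number of farms.
#' @param capacity_range_mw length-2 positive range of capacities.
#' @param status_probs probabilities for `operating`, `under_construction`,
#'   `proposed` (in that order; normalised internally).
#' @param seed integer seed.
#' @return data.frame `name`, `x`, `y`, `capacity_mw`, `status`.
#' @export
make_windfarms <- function(extent, n_farms = 10,
                           capacity_range_mw = c(20, 400),
                           status_probs = c(1, 1, 1) / 3, seed = 1) {
  if (length(extent) != 2 || any(!is.finite(extent)) || any(extent <= 0))
    stop("invalid extent")
  if (any(capacity_range_mw <= 0)) stop("capacities must be positive")
  set.seed(seed)
  statuses <- c("operating", "under_construction", "proposed")
  data.frame(
    name = sprintf("farm_%02d", seq_len(n_farms)),
    x = stats::runif(n_farms, 0, extent[1]),
    y = stats::runif(n_farms, 0, extent[2]),
    capacity_mw = stats::runif(n_farms, capacity_range_mw[1],
                               capacity_range_mw[2]),
    status = sample(statuses, n_farms, replace = TRUE,
                    prob = status_probs / sum(status_probs)),
    stringsAsFactors = FALSE
  )
}
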