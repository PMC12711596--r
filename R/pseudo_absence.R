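#' Environmental-envelope suitability index
#'
#' Measures how close each cell's environment is to the centroid of the
#' presence records. Per layer j, `z_j = (x_j - mu_j) / sigma_j` with mean
#' and sd taken at the presence locations; the index is the negative mean
#' absolute z-distance, `-(1/p) * sum_j |z_j|`, so 0 (at the presence
#' centroid) is the maximum attainable and more negative is less
#' presence-like. Invariant to affine rescaling of any input layer.
#'
#' @param stack a `predictor_stack`.
#' @param presences occurrence data.frame with planar `lon`, `lat` (km).
#' @return object of class `envelope_index`: list with `surface`
#'   (`raster_grid`) and `presence_stats` (data.frame `layer`, `mean`, `sd`).
#' @export
envelope_index <- function(stack, presences) {
  pv <- extract_stack(stack, presences$lon, presences$lat)
  ok <- stats::complete.cases(pv)
  if (sum(ok) < 2L) stop("need at least two presence records on valid cells")
  pv <- pv[ok, , drop = FALSE]
  mu <- vapply(pv, mean, numeric(1))
  sdv <- vapply(pv, stats::sd, numeric(1))
  use <- sdv > 0
  if (!all(use))
    warning("skipping zero-variance layer(s) at presences: ",
            paste(names(stack$layers)[!use], collapse = ", "))
  if (!any(use)) stop("no layer has positive variance at presences")
  tpl <- stack$layers[[1]]
  acc <- matrix(0, nrow(tpl$values), ncol(tpl$values))
  for (nm in names(stack$layers)[use])
    acc <- acc + abs((stack$layers[[nm]]$values - mu[[nm]]) / sdv[[nm]])
  idx <- -acc / sum(use)
  idx[!is.finite(tpl$values)] <- NA_real_
  structure(list(surface = raster_grid(idx, tpl$xmin, tpl$ymin, tpl$cellsize),
                 presence_stats = data.frame(layer = names(stack$layers),
                                             mean = unname(mu),
                                             sd = unname(sdv))),
            class = "envelope_index")
}

#' Split the study area into low- and high-suitability zones
#'
#' The threshold is the median envelope-index value at the presence
#' locations; cells strictly below it form the low-suitability zone (value
#' 0, eligible for pseudo-absences) and cells at or above it the
#' high-suitability zone (value 1).
#'
#' @param index an `envelope_index`.
#' @param presences occurrence data.frame (`lon`, `lat` planar km).
#' @return a `raster_grid` of 0/1 zone labels (nodata propagated), with the
#'   threshold attached as attribute `"threshold"`.
#' @export
split_zones <- function(index, presences) {
  surf <- index$surface
  pi_ <- extract_values(surf, presences$lon, presences$lat)
  pi_ <- pi_[is.finite(pi_)]
  if (length(pi_) == 0L) stop("no presence falls on a valid index cell")
  t <- stats::median(pi_)
  z <- ifelse(surf$values >= t, 1, 0)
  z[!is.finite(surf$values)] <- NA_real_
  out <- raster_grid(z, surf$xmin, surf$ymin, surf$cellsize)
  attr(out, "threshold") <- t
  out
}

#' Survey-effort surface from target-group records
#'
#' Rasterises target-group occurrence counts per cell, then applies a
#' square focal mean (default 3 x 3 cells; edge cells average over their
#' available neighbours) to smooth over-represented survey locations.
#'
#' @param target_group occurrence data.frame (`lon`, `lat` planar km).
#' @param template `raster_grid` defining the grid.
#' @param window focal window side in cells (default 3).
#' @return object of class `survey_effort`: list with `surface`
#'   (`raster_grid`) and `max_effort`.
#' @export
survey_effort <- function(target_group, template, window = 3) {
  if (nrow(target_group) == 0L) stop("target group is empty")
  rc <- cell_of(template, target_group$lon, target_group$lat)
  rc <- rc[!is.na(rc[, 1]), , drop = FALSE]
  if (nrow(rc) == 0L) stop("no target-group record falls on the grid")
  counts <- matrix(0, nrow(template$values), ncol(template$values))
  for (k in seq_len(nrow(rc)))
    counts[rc[k, 1], rc[k, 2]] <- counts[rc[k, 1], rc[k, 2]] + 1
  counts[!is.finite(template$values)] <- NA_real_
  sm <- focal_mean(raster_grid(counts, template$xmin, template$ymin,
                               template$cellsize), window)
  mx <- max(sm$values, na.rm = TRUE)
  if (mx <= 0) stop("survey effort surface is all zero")
  structure(list(surface = sm, max_effort = mx), class = "survey_effort")
}

#' Bias-corrected replicated pseudo-absence sampling
#'
#' Candidate cells are the low-suitability zone, minus presence cells, with
#' smoothed survey effort of at least `effort_floor` times the maximum
#' effort (under-surveyed areas are excluded so absence of records is
#' evidence of absence, not of absent observers). If fewer than `n`
#' candidates remain the floor is relaxed by `relax_step` at a time (down to
#' 0); if still short, cells are drawn with replacement and the result is
#' flagged degraded. Each replicate draws `n` cells uniformly (without
#' replacement unless degraded) under a seed derived from `seed`, and each
#' replicate's points carry presences (weight 1) and pseudo-absences
#' (weight `n_presence / n`) so the two classes have equal summed weight.
#'
#' @param low_zone 0/1 `raster_grid` from [split_zones()] (0 = low zone).
#' @param effort a `survey_effort`.
#' @param presences occurrence data.frame (`lon`, `lat` planar km).
#' @param n pseudo-absences per replicate (default 10000).
#' @param effort_floor starting effort floor as a fraction of the maximum
#'   effort (default 0.40).
#' @param replicates number of pseudo-absence replicates (default 3).
#' @param relax_step floor decrement used when candidates run short
#'   (default 0.05).
#' @param seed integer master seed.
#' @return object of class `pa_set`: data.frame `x`, `y`, `label`, `weight`,
#'   `replicate_id`, with attributes `n_presence`, `floor_used`,
#'   `n_candidates`, `degraded`.
#' @export
sample_pseudo_absences <- function(low_zone, effort, presences, n = 10000,
                                   effort_floor = 0.40, replicates = 3,
                                   relax_step = 0.05, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  eff <- effort$surface
  if (!same_grid(low_zone, eff)) stop("zone and effort grids differ")
  low <- as.vector(low_zone$values) == 0
  low[is.na(low)] <- FALSE
  if (!any(low)) stop("low-suitability zone is empty")
  pres_rc <- cell_of(low_zone, presences$lon, presences$lat)
  pres_idx <- pres_rc[, 1] + (pres_rc[, 2] - 1L) * nrow(low_zone$values)
  pres_idx <- unique(pres_idx[!is.na(pres_idx)])
  ev <- as.vector(eff$values)
  eligible <- function(floor) {
    cand <- low & is.finite(ev) & ev >= floor * effort$max_effort
    cand[pres_idx] <- FALSE
    which(cand)
  }
  floor_used <- effort_floor
  cand <- eligible(floor_used)
  while (length(cand) < n && floor_used > 0) {
    floor_used <- max(0, floor_used - relax_step)
    cand <- eligible(floor_used)
  }
  degraded <- length(cand) < n
  if (degraded)
    warning(sprintf(paste0("only %d candidate cells for %d pseudo-absences ",
                           "at floor 0; sampling with replacement"),
                    length(cand), n))
  ctr <- grid_centers(low_zone)
  n_presence <- nrow(presences)
  reps <- lapply(seq_len(replicates), function(r) {
    set.seed(derive_seed(seed, "pa_replicate", r))
    pick <- if (length(cand) == n && !degraded) cand
            else sample(cand, n, replace = degraded)
    rbind(
      data.frame(x = presences$lon, y = presences$lat,
                 label = rep(1, n_presence), weight = rep(1, n_presence),
                 replicate_id = rep(r, n_presence)),
      data.frame(x = ctr$x[pick], y = ctr$y[pick], label = 0,
                 weight = n_presence / n, replicate_id = r)
    )
  })
  out <- do.call(rbind, reps)
  rownames(out) <- NULL
  structure(out, class = c("pa_set", "data.frame"),
            n_presence = n_presence, floor_used = floor_used,
            n_candidates = length(cand), degraded = degraded)
}

#' @export
print.pa_set <- function(x, ...) {
  cat(sprintf(paste0("<pa_set> %d presences, %d pseudo-absences per ",
                     "replicate, %d replicate(s)\n"),
              attr(x, "n_presence"),
              sum(x$label == 0 & x$replicate_id == x$replicate_id[1]),
              length(unique(x$replicate_id))))
  cat(sprintf("  effort floor used: %.2f (candidates: %d%s)\n",
              attr(x, "floor_used"), attr(x, "n_candidates"),
              if (isTRUE(attr(x, "degraded"))) ", DEGRADED (with replacement)"
              else ""))
  invisible(x)
}
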