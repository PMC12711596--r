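#' Project an ensemble onto a scenario climate
#'
#' Averages the scenario's GCM stacks cell-wise ([gcm_mean()]), predicts the
#' ensemble suitability on the averaged stack, and binarises at the SAME
#' threshold as the current-climate map, so current/future differences
#' reflect the climate signal and not threshold drift.
#'
#' @param object an `esdm` fit.
#' @param gcm_stacks list of `predictor_stack` objects (one per GCM), or a
#'   single `predictor_stack`.
#' @param threshold binarisation threshold; defaults to the fit's pooled
#'   holdout max-TSS threshold.
#' @return list with `suitability` (continuous `raster_grid`) and `binary`
#'   (0/1 `raster_grid`).
#' @export
project_scenario <- function(object, gcm_stacks, threshold = NULL) {
  if (inherits(gcm_stacks, "predictor_stack")) gcm_stacks <- list(gcm_stacks)
  avg <- gcm_mean(gcm_stacks)
  if (is.null(threshold)) threshold <- object$threshold
  suit <- predict(object, avg)
  list(suitability = suit, binary = binarise(suit, threshold))
}

#' Classify current-vs-future habitat change
#'
#' Cell codes: 0 = stable unsuitable, 1 = stable suitable, 2 = loss
#' (suitable now, not in future), 3 = gain (the reverse); nodata where
#' either map is nodata.
#'
#' @param current,future co-registered 0/1 `raster_grid` maps.
#' @return a `raster_grid` of class codes with attribute `"classes"`.
#' @export
change_map <- function(current, future) {
  if (!same_grid(current, future)) stop("maps are not co-registered")
  cu <- current$values; fu <- future$values
  v <- matrix(NA_real_, nrow(cu), ncol(cu))
  ok <- is.finite(cu) & is.finite(fu)
  v[ok & cu == 0 & fu == 0] <- 0
  v[ok & cu == 1 & fu == 1] <- 1
  v[ok & cu == 1 & fu == 0] <- 2
  v[ok & cu == 0 & fu == 1] <- 3
  out <- raster_grid(v, current$xmin, current$ymin, current$cellsize)
  attr(out, "classes") <- c(`0` = "stable_unsuitable",
                            `1` = "stable_suitable",
                            `2` = "loss", `3` = "gain")
  out
}

#' Habitat-change accounting
#'
#' @param cm a [change_map()] raster.
#' @param pixel_area_km2 area of one cell in km2.
#' @return list with cell counts, areas in km2 (`stable_suitable_km2`,
#'   `loss_km2`, `gain_km2`, `net_km2`) and `net_pct` =
#'   `(gain - loss) / current suitable * 100`.
#' @export
change_stats <- function(cm, pixel_area_km2) {
  v <- cm$values
  n <- c(stable_unsuitable = sum(v == 0, na.rm = TRUE),
         stable_suitable = sum(v == 1, na.rm = TRUE),
         loss = sum(v == 2, na.rm = TRUE),
         gain = sum(v == 3, na.rm = TRUE))
  current_suitable <- n[["stable_suitable"]] + n[["loss"]]
  net <- n[["gain"]] - n[["loss"]]
  list(counts = n,
       stable_suitable_km2 = n[["stable_suitable"]] * pixel_area_km2,
       loss_km2 = n[["loss"]] * pixel_area_km2,
       gain_km2 = n[["gain"]] * pixel_area_km2,
       net_km2 = net * pixel_area_km2,
       current_suitable_km2 = current_suitable * pixel_area_km2,
       net_pct = if (current_suitable > 0) 100 * net / current_suitable
                 else NA_real_)
}
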