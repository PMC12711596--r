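#' Per-zone suitable-area accounting
#'
#' A raster cell belongs to the zone polygon containing its centre
#' (even-odd rule; the Voronoi tiles of [make_zones()] partition the cells
#' exactly). Suitable area is the count of suitable cells times
#' `pixel_area_km2`.
#'
#' @param binary 0/1 suitability `raster_grid`.
#' @param zones a `zone_set` (see [make_zones()]) or list with `labels` and
#'   `polygons`.
#' @param pixel_area_km2 area of one cell in km2 (default `cellsize^2`).
#' @return data.frame `zone`, `zone_cells`, `suitable_cells`,
#'   `suitable_km2`, `zone_km2`, `percent` (`NA` for zones whose cells are
#'   all nodata or that contain no cell).
#' @export
zonal_suitable <- function(binary, zones, pixel_area_km2 = NULL) {
  if (is.null(pixel_area_km2)) pixel_area_km2 <- binary$cellsize^2
  ctr <- grid_centers(binary)
  v <- as.vector(binary$values)
  zone_id <- rep(NA_integer_, nrow(ctr))
  for (z in seq_along(zones$polygons)) {
    poly <- zones$polygons[[z]]
    if (is.null(poly) || nrow(poly) < 3) next
    hit <- point_in_polygon(ctr$x, ctr$y, poly) & is.na(zone_id)
    zone_id[hit] <- z
  }
  out <- lapply(seq_along(zones$labels), function(z) {
    in_z <- which(zone_id == z)
    valid <- in_z[is.finite(v[in_z])]
    suit <- sum(v[valid] == 1)
    data.frame(zone = zones$labels[z],
               zone_cells = length(valid),
               suitable_cells = suit,
               suitable_km2 = suit * pixel_area_km2,
               zone_km2 = length(valid) * pixel_area_km2,
               percent = if (length(valid) > 0) 100 * suit / length(valid)
                         else NA_real_)
  })
  do.call(rbind, out)
}

#' Cleared land area of a wind-energy project
#'
#' Land clearing of about 0.3 ha per MW of installed capacity.
#'
#' @param capacity_mw installed capacity in MW (positive).
#' @return cleared area in hectares.
#' @export
cleared_area <- function(capacity_mw) {
  if (any(!is.finite(capacity_mw)) || any(capacity_mw <= 0))
    stop("capacity must be positive")
  0.3 * capacity_mw
}

#' Circular clearing-footprint buffer of a wind farm
#'
#' Disc centred on the farm whose area equals the cleared area implied by
#' its capacity: radius `sqrt(area_km2 / pi)` with
#' `area_km2 = cleared_area(capacity) / 100`.
#'
#' @param x,y farm location (km).
#' @param capacity_mw installed capacity (MW).
#' @param n_segments polygon discretisation (default 64).
#' @return list with `center`, `radius_km`, `area_km2` and `polygon`
#'   (vertex matrix).
#' @export
farm_buffer <- function(x, y, capacity_mw, n_segments = 64) {
  area_km2 <- cleared_area(capacity_mw) / 100
  r <- sqrt(area_km2 / pi)
  th <- seq(0, 2 * pi, length.out = n_segments + 1)[-(n_segments + 1)]
  list(center = c(x = x, y = y), radius_km = r, area_km2 = area_km2,
       polygon = cbind(x + r * cos(th), y + r * sin(th)))
}

#' Wind-farm footprint / suitable-habitat overlap
#'
#' For each farm, counts the suitable cells whose centres fall inside the
#' farm's circular clearing buffer (exact centre-in-disc test), converts
#' counts to km2 with `pixel_area_km2`, and aggregates by development
#' status: `percent = suitable km2 / total cleared km2 x 100`. Because whole
#' pixels are counted, buffers smaller than a pixel contribute either the
#' full containing pixel or nothing (documented quantisation). Farms outside
#' the raster extent are excluded with a warning and reported.
#'
#' @param binary 0/1 suitability `raster_grid`.
#' @param farms data.frame `name`, `x`, `y`, `capacity_mw`, `status`.
#' @param pixel_area_km2 km2 per pixel (default 0.8606, the area of a
#'   30-arc-second pixel at mid-latitudes; use `cellsize^2` on synthetic
#'   planar landscapes).
#' @return list with `per_farm` (data.frame incl. `suitable_cells`,
#'   `suitable_km2`, `cleared_km2`), `by_status` (data.frame `status`,
#'   `cleared_km2`, `suitable_km2`, `percent`), `merged_percent` (variant
#'   counting each suitable cell once across the union of buffers) and
#'   `excluded` (farm names outside the extent).
#' @export
windfarm_overlap <- function(binary, farms, pixel_area_km2 = 0.8606) {
  statuses <- c("operating", "under_construction", "proposed")
  if (!all(farms$status %in% statuses))
    stop("farm status must be one of: ", paste(statuses, collapse = ", "))
  if (any(farms$capacity_mw <= 0)) stop("capacity must be positive")
  nr <- nrow(binary$values); nc <- ncol(binary$values)
  xmax <- binary$xmin + nc * binary$cellsize
  ymax <- binary$ymin + nr * binary$cellsize
  inside <- farms$x >= binary$xmin & farms$x <= xmax &
    farms$y >= binary$ymin & farms$y <= ymax
  excluded <- farms$name[!inside]
  if (length(excluded))
    warning("farm(s) outside raster extent excluded: ",
            paste(excluded, collapse = ", "))
  farms <- farms[inside, , drop = FALSE]
  ctr <- grid_centers(binary)
  v <- as.vector(binary$values)
  suitable <- which(v == 1 & is.finite(v))
  union_cells <- integer(0)
  per <- lapply(seq_len(nrow(farms)), function(i) {
    b <- farm_buffer(farms$x[i], farms$y[i], farms$capacity_mw[i])
    d2 <- (ctr$x[suitable] - farms$x[i])^2 + (ctr$y[suitable] - farms$y[i])^2
    hit <- suitable[d2 <= b$radius_km^2]
    union_cells <<- union(union_cells, hit)
    data.frame(name = farms$name[i], status = farms$status[i],
               capacity_mw = farms$capacity_mw[i],
               cleared_km2 = b$area_km2,
               suitable_cells = length(hit),
               suitable_km2 = length(hit) * pixel_area_km2)
  })
  per <- if (length(per)) do.call(rbind, per) else
    data.frame(name = character(0), status = character(0),
               capacity_mw = numeric(0), cleared_km2 = numeric(0),
               suitable_cells = integer(0), suitable_km2 = numeric(0))
  by_status <- do.call(rbind, lapply(statuses, function(s) {
    sub <- per[per$status == s, , drop = FALSE]
    cl <- sum(sub$cleared_km2); su <- sum(sub$suitable_km2)
    data.frame(status = s, n_farms = nrow(sub), cleared_km2 = cl,
               suitable_km2 = su,
               percent = if (cl > 0) 100 * su / cl else NA_real_)
  }))
  total_cleared <- sum(per$cleared_km2)
  list(per_farm = per, by_status = by_status,
       merged_percent = if (total_cleared > 0)
         100 * length(union_cells) * pixel_area_km2 / total_cleared
       else NA_real_,
       excluded = excluded)
}

#' Nominal area of a 30-arc-second pixel
#'
#' The square of 30 arc-seconds of arc length on a sphere of the WGS84
#' equatorial radius: `(6378.137 km x 30" in radians)^2` — approximately
#' 0.8606 km2, the conversion factor for ~1 km climate-grid pixels at
#' mid-latitudes.
#'
#' @param radius_km sphere radius (default 6378.137).
#' @return pixel area in km2.
#' @export
pixel_area_30arcsec <- function(radius_km = 6378.137) {
  (radius_km * (30 / 3600) * pi / 180)^2
}
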