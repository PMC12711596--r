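#' Clean a raw occurrence table
#'
#' Multi-step filtration applied in a fixed order, each step counted in the
#' returned report:
#' \enumerate{
#'   \item keep human-observation records only (`basis_of_record`,
#'     case/space-insensitive; if the column is absent all records pass);
#'   \item drop records with missing coordinates;
#'   \item drop exact duplicates of (species, lon, lat, date);
#'   \item drop equal-coordinate errors (`lon == lat` exactly);
#'   \item drop records outside `date_range` (records with no parseable date
#'     pass);
#'   \item drop records over nodata cells of `valid_mask` or off its extent
#'     (the sea/out-of-area analogue).
#' }
#'
#' @param raw data.frame with columns `lon`, `lat` and optionally `id`,
#'   `species`, `date`, `basis_of_record`.
#' @param valid_mask `raster_grid`; cells with non-finite values are invalid.
#'   `NULL` skips the mask filter.
#' @param date_range length-2 vector of years (default `c(1970, 2024)`).
#' @return list with `occurrences` (cleaned data.frame) and `report`
#'   (data.frame `filter`, `removed`, in application order).
#' @export
clean_occurrences <- function(raw, valid_mask = NULL,
                              date_range = c(1970, 2024)) {
  if (nrow(raw) == 0L) stop("raw occurrence table is empty")
  occ <- raw
  report <- data.frame(filter = character(0), removed = integer(0))
  note <- function(name, before, after) {
    report <<- rbind(report,
                     data.frame(filter = name, removed = before - after))
  }

  if ("basis_of_record" %in% names(occ)) {
    n0 <- nrow(occ)
    b <- tolower(gsub("[ _]", "", occ$basis_of_record))
    occ <- occ[!is.na(b) & b == "humanobservation", , drop = FALSE]
    note("non_human_observation", n0, nrow(occ))
  } else note("non_human_observation", 0L, 0L)

  n0 <- nrow(occ)
  occ <- occ[is.finite(occ$lon) & is.finite(occ$lat), , drop = FALSE]
  note("missing_coordinates", n0, nrow(occ))

  n0 <- nrow(occ)
  key <- paste(if ("species" %in% names(occ)) occ$species else "",
               occ$lon, occ$lat,
               if ("date" %in% names(occ)) occ$date else "", sep = "\r")
  occ <- occ[!duplicated(key), , drop = FALSE]
  note("duplicate_records", n0, nrow(occ))

  n0 <- nrow(occ)
  occ <- occ[occ$lon != occ$lat, , drop = FALSE]
  note("equal_coordinates", n0, nrow(occ))

  if ("date" %in% names(occ)) {
    n0 <- nrow(occ)
    yr <- occurrence_year(occ$date)
    keep <- is.na(yr) | (yr >= date_range[1] & yr <= date_range[2])
    occ <- occ[keep, , drop = FALSE]
    note("out_of_date_range", n0, nrow(occ))
  } else note("out_of_date_range", 0L, 0L)

  if (!is.null(valid_mask)) {
    n0 <- nrow(occ)
    v <- extract_values(valid_mask, occ$lon, occ$lat)
    occ <- occ[is.finite(v), , drop = FALSE]
    note("outside_valid_mask", n0, nrow(occ))
  } else note("outside_valid_mask", 0L, 0L)

  if (nrow(occ) == 0L) warning("all records removed by cleaning")
  rownames(occ) <- NULL
  list(occurrences = occ, report = report)
}

occurrence_year <- function(x) {
  if (is.numeric(x)) return(x)
  d <- suppressWarnings(as.Date(as.character(x)))
  yr <- as.numeric(format(d, "%Y"))
  # bare years ("1999") fail as.Date; fall back to a numeric parse
  bare <- is.na(yr)
  yr[bare] <- suppressWarnings(as.numeric(as.character(x)[bare]))
  yr
}

#' Spatially thin occurrences to one record per grid cell
#'
#' Overlays a square thinning grid (default 15 km, the scale of the target
#' species' home range) and keeps exactly one record per occupied cell,
#' chosen uniformly at random under `seed`. Output rows are ordered by cell
#' index so reruns are stable; thinning an already-thinned table is a no-op.
#'
#' @param occ occurrence data.frame with planar `lon`, `lat` in km.
#' @param cell_km thinning grid cell size in km (default 15).
#' @param origin length-2 grid anchor (default `c(0, 0)`, the raster origin).
#' @param seed integer seed for the within-cell choice.
#' @param crs `"planar"` (required) or `"geographic"`; geographic coordinates
#'   must be projected before thinning and raise an error.
#' @return thinned occurrence data.frame.
#' @export
thin_occurrences <- function(occ, cell_km = 15, origin = c(0, 0), seed = 1,
                             crs = c("planar", "geographic")) {
  crs <- match.arg(crs)
  if (crs == "geographic")
    stop("thinning requires planar km coordinates; project the data first")
  if (cell_km <= 0) stop("cell_km must be positive")
  if (nrow(occ) == 0L) return(occ)
  cx <- floor((occ$lon - origin[1]) / cell_km)
  cy <- floor((occ$lat - origin[2]) / cell_km)
  cell <- paste(cx, cy, sep = ":")
  set.seed(seed)
  keep <- vapply(split(seq_len(nrow(occ)), cell), function(ix) {
    if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
  }, integer(1))
  ord <- order(cx[keep], cy[keep])
  out <- occ[keep[ord], , drop = FALSE]
  rownames(out) <- NULL
  out
}
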