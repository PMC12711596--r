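#' Write a raster to an ESRI ASCII grid file
#'
#' Plain-text interchange format for single-band grids (readable by the
#' usual GIS stacks). Nodata cells are written as `-9999`.
#'
#' @param r a `raster_grid`.
#' @param path output file path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path) {
  v <- r$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(v)),
               sprintf("nrows %d", nrow(v)),
               sprintf("xllcorner %.10g", r$xmin),
               sprintf("yllcorner %.10g", r$ymin),
               sprintf("cellsize %.10g", r$cellsize),
               "NODATA_value -9999"), con)
  for (i in rev(seq_len(nrow(v)))) {  # ASCII grids run north to south
    row <- v[i, ]
    row[!is.finite(row)] <- -9999
    writeLines(paste(format(row, trim = TRUE, digits = 10),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid file
#' @param path file path.
#' @return a `raster_grid` (`-9999` and the declared nodata become `NA`).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  body <- lines[i:length(lines)]
  vals <- lapply(body, function(l)
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]]))
  m <- do.call(rbind, vals)
  nodata <- hdr$nodata_value %||% -9999
  m[m == nodata] <- NA_real_
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # back to south-up storage
  raster_grid(m, hdr$xllcorner %||% 0, hdr$yllcorner %||% 0,
              hdr$cellsize %||% 1)
}

#' Write occurrences to CSV
#' @param occ occurrence data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ, path, row.names = FALSE)
  invisible(path)
}

#' Read occurrences from CSV
#' @param path CSV path with at least `species`, `lon`, `lat`.
#' @return occurrence data.frame.
#' @export
read_occurrences <- function(path) {
  occ <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lon", "lat")
  if (!all(need %in% names(occ)))
    stop("occurrence CSV must have columns: ", paste(need, collapse = ", "))
  occ
}

#' Write a zone set to GeoJSON
#' @param zones a `zone_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_zones_geojson <- function(zones, path) {
  features <- lapply(seq_along(zones$labels), function(i) {
    poly <- zones$polygons[[i]]
    ring <- rbind(poly, poly[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(label = zones$labels[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(k)
                                                     unname(ring[k, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Read a zone set from GeoJSON (simple polygons, first ring only)
#' @param path GeoJSON path.
#' @return a `zone_set`.
#' @export
read_zones_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  labels <- character(0); polys <- list()
  for (f in g$features) {
    labels <- c(labels, f$properties$label %||% paste0("zone_",
                                                       length(labels) + 1))
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ]))
      m <- m[-nrow(m), , drop = FALSE]
    polys <- c(polys, list(m))
  }
  structure(list(labels = labels, seeds = NULL, polygons = polys),
            class = "zone_set")
}

#' Write wind farms to GeoJSON points
#' @param farms wind-farm data.frame (`name`, `x`, `y`, `capacity_mw`,
#'   `status`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_windfarms_geojson <- function(farms, path) {
  features <- lapply(seq_len(nrow(farms)), function(i)
    list(type = "Feature",
         properties = list(name = farms$name[i],
                           capacity_mw = farms$capacity_mw[i],
                           status = farms$status[i]),
         geometry = list(type = "Point",
                         coordinates = c(farms$x[i], farms$y[i]))))
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Read wind farms from GeoJSON points
#' @param path GeoJSON path.
#' @return wind-farm data.frame.
#' @export
read_windfarms_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  do.call(rbind, lapply(g$features, function(f)
    data.frame(name = f$properties$name,
               x = f$geometry$coordinates[[1]],
               y = f$geometry$coordinates[[2]],
               capacity_mw = f$properties$capacity_mw,
               status = f$properties$status,
               stringsAsFactors = FALSE)))
}
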