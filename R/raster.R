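#' Planar single-band raster grid
#'
#' The spatial currency of the package: a numeric matrix of cell values plus
#' a planar georeference (origin of the lower-left corner and a square cell
#' size, both in km). Row `i` of the matrix is the i-th row of cells counted
#' from the bottom edge; column `j` runs west to east. `NA` cells are nodata.
#'
#' @param values numeric matrix of cell values (`NA` = nodata).
#' @param xmin,ymin planar coordinates (km) of the lower-left corner.
#' @param cellsize side length of a (square) cell in km.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin = 0, ymin = 0, cellsize = 1) {
  values <- as.matrix(values)
  if (!is.numeric(cellsize) || length(cellsize) != 1L || !is.finite(cellsize) ||
      cellsize <= 0)
    stop("'cellsize' must be a single positive number")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("raster must have at least one cell")
  storage.mode(values) <- "double"
  dimnames(values) <- NULL
  structure(list(values = values, xmin = xmin, ymin = ymin,
                 cellsize = cellsize),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid> %d rows x %d cols, cell %.4g km\n",
              nrow(v), ncol(v), x$cellsize))
  cat(sprintf("  extent: x [%.4g, %.4g], y [%.4g, %.4g] km\n",
              x$xmin, x$xmin + ncol(v) * x$cellsize,
              x$ymin, x$ymin + nrow(v) * x$cellsize))
  ok <- is.finite(v)
  cat(sprintf("  values: [%.4g, %.4g], %d/%d valid cells\n",
              suppressWarnings(min(v[ok])), suppressWarnings(max(v[ok])),
              sum(ok), length(v)))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Do two rasters share shape, origin and cell size?
#' @param a,b `raster_grid` objects.
#' @return logical.
#' @export
same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xmin, a$ymin, a$cellsize),
                     c(b$xmin, b$ymin, b$cellsize), tolerance = 1e-9))
}

#' Cell-centre coordinates of every cell
#'
#' Returned in the matrix storage (column-major) order, so `grid_centers(r)$x`
#' lines up with `as.vector(r$values)`.
#'
#' @param r a `raster_grid`.
#' @return data.frame with columns `x`, `y` (km).
#' @export
grid_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values); cs <- r$cellsize
  data.frame(
    x = rep(r$xmin + (seq_len(nc) - 0.5) * cs, each = nr),
    y = rep(r$ymin + (seq_len(nr) - 0.5) * cs, times = nc)
  )
}

#' Row/column indices of the cells containing planar points
#'
#' Cells are half-open: a point on a shared edge belongs to the cell to its
#' north-east, matching `floor((coord - origin) / cellsize)`.
#'
#' @param r a `raster_grid`.
#' @param x,y point coordinates (km).
#' @return integer matrix with columns `row`, `col`; `NA` rows for points
#'   outside the extent.
#' @export
cell_of <- function(r, x, y) {
  nr <- nrow(r$values); nc <- ncol(r$values); cs <- r$cellsize
  col <- floor((x - r$xmin) / cs) + 1
  row <- floor((y - r$ymin) / cs) + 1
  bad <- !is.finite(row) | !is.finite(col) |
    row < 1 | row > nr | col < 1 | col > nc
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Extract raster values at planar points
#' @param r a `raster_grid`.
#' @param x,y point coordinates (km).
#' @return numeric vector; `NA` for points off the grid or over nodata.
#' @export
extract_values <- function(r, x, y) {
  rc <- cell_of(r, x, y)
  out <- rep(NA_real_, nrow(rc))
  ok <- !is.na(rc[, 1])
  out[ok] <- r$values[rc[ok, , drop = FALSE]]
  out
}

#' Focal (moving-window) mean
#'
#' Square window of `window` x `window` cells. Edge and corner cells average
#' over the neighbours that exist (partial-window mean); `NA` cells are
#' excluded from both numerator and denominator and stay `NA` in the output.
#'
#' @param r a `raster_grid`.
#' @param window odd window side length in cells (default 3).
#' @return a `raster_grid` on the same grid.
#' @export
focal_mean <- function(r, window = 3) {
  if (window %% 2 != 1 || window < 1) stop("'window' must be a positive odd integer")
  v <- r$values
  nr <- nrow(v); nc <- ncol(v)
  h <- (window - 1) / 2
  ok <- is.finite(v)
  vz <- ifelse(ok, v, 0)
  s <- matrix(0, nr, nc); n <- matrix(0, nr, nc)
  for (di in -h:h) {
    ri <- intersect(seq_len(nr), seq_len(nr) + di)  # target rows with a source
    si <- ri - di
    for (dj in -h:h) {
      cj <- intersect(seq_len(nc), seq_len(nc) + dj)
      sj <- cj - dj
      s[ri, cj] <- s[ri, cj] + vz[si, sj]
      n[ri, cj] <- n[ri, cj] + ok[si, sj]
    }
  }
  out <- ifelse(n > 0, s / n, NA_real_)
  out[!ok] <- NA_real_
  raster_grid(out, r$xmin, r$ymin, r$cellsize)
}

# Gaussian blur with edge renormalisation via dense separable smoothing
# matrices; sd = radius cells, kernel truncated at 3 sd.
gaussian_blur <- function(mat, radius) {
  if (radius <= 0) return(mat)
  smoother <- function(n) {
    idx <- seq_len(n)
    K <- exp(-outer(idx, idx, "-")^2 / (2 * radius^2))
    K[abs(outer(idx, idx, "-")) > ceiling(3 * radius)] <- 0
    K / rowSums(K)
  }
  Kr <- smoother(nrow(mat)); Kc <- smoother(ncol(mat))
  Kr %*% mat %*% t(Kc)
}

#' @export
as.data.frame.raster_grid <- function(x, ...) {
  cbind(grid_centers(x), value = as.vector(x$values))
}
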