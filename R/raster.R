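#' Gridded raster in geographic coordinates
#'
#' A minimal in-memory raster: a numeric matrix on a regular lon/lat grid.
#' Row 1 is the northernmost row and column 1 the westernmost column, the
#' same orientation as an ESRI ASCII grid file.  `NA` cells are nodata.
#'
#' @param values numeric matrix (rows = latitude bands, north first).
#' @param xllcorner,yllcorner lower-left corner of the grid, degrees.
#' @param cellsize cell edge length in degrees (square cells).
#' @return An object of class `env_raster`.
#' @export
env_raster <- function(values, xllcorner, yllcorner, cellsize) {
  stopifnot(is.matrix(values), is.numeric(cellsize), cellsize > 0)
  structure(
    list(values = values, xllcorner = xllcorner, yllcorner = yllcorner,
         cellsize = cellsize),
    class = "env_raster"
  )
}

#' @export
#' @method print env_raster
print.env_raster <- function(x, ...) {
  cat(sprintf("<env_raster> %d rows x %d cols, cellsize %g deg\n",
              nrow(x$values), ncol(x$values), x$cellsize))
  cat(sprintf("  extent: lon [%g, %g], lat [%g, %g]; %d nodata cells\n",
              x$xllcorner, x$xllcorner + ncol(x$values) * x$cellsize,
              x$yllcorner, x$yllcorner + nrow(x$values) * x$cellsize,
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.env_raster <- function(x) dim(x$values)

#' Cell-center coordinates of a raster
#'
#' @param r an `env_raster`.
#' @return `raster_lons`: vector of column-center longitudes (west to east);
#'   `raster_lats`: vector of row-center latitudes (north to south, matching
#'   matrix row order); `raster_coords`: data frame with one row per cell in
#'   column-major matrix order (`lon`, `lat`, `row`, `col`).
#' @export
raster_lons <- function(r) {
  r$xllcorner + (seq_len(ncol(r$values)) - 0.5) * r$cellsize
}

#' @rdname raster_lons
#' @export
raster_lats <- function(r) {
  nr <- nrow(r$values)
  r$yllcorner + (nr - seq_len(nr) + 0.5) * r$cellsize
}

#' @rdname raster_lons
#' @export
raster_coords <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  data.frame(
    lon = rep(raster_lons(r), each = nr),
    lat = rep(raster_lats(r), times = nc),
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr)
  )
}

#' Locate points on a raster grid
#'
#' @param r an `env_raster`.
#' @param lon,lat point coordinates in degrees.
#' @return integer matrix with columns `row`, `col`; `NA` for points
#'   outside the extent.
#' @export
raster_cell_of <- function(r, lon, lat) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- floor((lon - r$xllcorner) / r$cellsize) + 1L
  row <- nr - floor((lat - r$yllcorner) / r$cellsize)
  # points exactly on the top/right edge belong to the outermost cell
  col[lon == r$xllcorner + nc * r$cellsize] <- nc
  row[lat == r$yllcorner + nr * r$cellsize] <- 1L
  bad <- col < 1L | col > nc | row < 1L | row > nr |
    !is.finite(lon) | !is.finite(lat)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

same_grid <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$xllcorner - b$xllcorner) < tol &&
    abs(a$yllcorner - b$yllcorner) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Multi-layer environmental stack
#'
#' A named list of [env_raster] layers sharing one grid.
#'
#' @param layers named list of `env_raster` objects.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1,
            !is.null(names(layers)), all(nzchar(names(layers))))
  for (l in layers) stopifnot(inherits(l, "env_raster"))
  for (l in layers[-1]) {
    if (!same_grid(layers[[1]], l)) stop("all layers must share one grid")
  }
  structure(list(layers = layers), class = "env_stack")
}

#' @export
#' @method print env_stack
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d layers: %s\n", length(x$layers),
              paste(names(x$layers), collapse = ", ")))
  print(x$layers[[1]])
  invisible(x)
}

#' @export
names.env_stack <- function(x) names(x$layers)

#' Stack cell values as a matrix
#'
#' @param stack an `env_stack`.
#' @param complete drop cells with nodata in any layer.
#' @return list with `x` (cells x layers matrix), `cell` (matrix indices of
#'   the rows, column-major order of the underlying matrices) and `coords`.
#' @export
stack_values <- function(stack, complete = TRUE) {
  x <- vapply(stack$layers, function(l) as.vector(l$values),
              numeric(length(stack$layers[[1]]$values)))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(stack$layers)))
  co <- raster_coords(stack$layers[[1]])
  keep <- if (complete) stats::complete.cases(x) else rep(TRUE, nrow(x))
  list(x = x[keep, , drop = FALSE],
       cell = as.matrix(co[keep, c("row", "col")]),
       coords = co[keep, c("lon", "lat")])
}

#' Extract stack values at point locations
#'
#' @param stack an `env_stack`.
#' @param points data frame with `lon` and `lat` columns.
#' @return matrix (points x layers); rows outside the extent are `NA`.
#' @export
extract_env <- function(stack, points) {
  r <- stack$layers[[1]]
  rc <- raster_cell_of(r, points$lon, points$lat)
  out <- vapply(stack$layers, function(l) {
    v <- rep(NA_real_, nrow(rc))
    ok <- !is.na(rc[, 1])
    v[ok] <- l$values[rc[ok, , drop = FALSE]]
    v
  }, numeric(nrow(rc)))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(rc),
                                     dimnames = list(NULL, names(stack$layers)))
  out
}
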