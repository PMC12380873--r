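#' Fisher-Jenks natural breaks
#'
#' Optimal partition of a 1-D distribution into `k` classes minimizing the
#' within-class sum of squared deviations, by exact dynamic programming
#' (compiled).  Returns the `k - 1` upper break values, i.e. the maximum
#' data value of each class but the last.
#'
#' @param values numeric vector with at least `k` distinct finite values.
#' @param k number of classes.
#' @return numeric vector of `k - 1` increasing break values.
#' @export
jenks_breaks <- function(values, k = 3) {
  v <- sort(values[is.finite(values)])
  if (length(unique(v)) < k) {
    stop(sprintf("need >= %d distinct values for %d classes", k, k))
  }
  if (k == 1) return(numeric(0))
  ends <- jenks_dp(v, as.integer(k))
  v[ends[-k]]
}

#' Classify a suitability raster by break values
#'
#' Half-open intervals `(-Inf, b1]`, `(b1, b2]`, ..., `(b_last, Inf)`:
#' a cell exactly at a break goes to the lower class.  Nodata propagates.
#'
#' @param raster an [env_raster] (e.g. consensus suitability).
#' @param breaks increasing break values (e.g. from [jenks_breaks()]).
#' @param labels class labels, `length(breaks) + 1`, lowest first; the
#'   default names the usual three suitability levels when there are two
#'   breaks and falls back to `class1`, `class2`, ... otherwise.
#' @return object of class `class_map`: `classes` (integer matrix, 1 =
#'   lowest), `labels`, `breaks`, plus the grid georeference.
#' @export
classify_suitability <- function(raster, breaks, labels = NULL) {
  stopifnot(inherits(raster, "env_raster"))
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop("breaks must be strictly increasing")
  }
  if (is.null(labels)) {
    labels <- if (length(breaks) == 2) c("unsuitable", "low", "high") else
      sprintf("class%d", seq_len(length(breaks) + 1))
  }
  if (length(labels) != length(breaks) + 1) {
    stop("need length(breaks) + 1 labels")
  }
  # left.open: a cell exactly at a break falls in the lower class
  cl <- matrix(findInterval(raster$values, breaks, left.open = TRUE) + 1L,
               nrow(raster$values), ncol(raster$values))
  cl[is.na(raster$values)] <- NA_integer_
  structure(list(classes = cl, labels = labels, breaks = breaks,
                 xllcorner = raster$xllcorner, yllcorner = raster$yllcorner,
                 cellsize = raster$cellsize),
            class = "class_map")
}

#' @export
#' @method print class_map
print.class_map <- function(x, ...) {
  cat(sprintf("<class_map> %d x %d cells, breaks at %s\n",
              nrow(x$classes), ncol(x$classes),
              paste(signif(x$breaks, 4), collapse = ", ")))
  print(table(factor(x$labels[x$classes], levels = x$labels),
              useNA = "ifany"))
  invisible(x)
}

classmap_raster <- function(cm) {
  env_raster(cm$classes + 0.0, cm$xllcorner, cm$yllcorner, cm$cellsize)
}

#' Spherical cell areas per latitude row
#'
#' Area of a lon/lat grid cell in the latitude band `[phi1, phi2]` with
#' longitudinal width `dlon`: `A = R^2 * dlon_rad * |sin(phi2) -
#' sin(phi1)|`, authalic Earth radius `R = 6371.0088` km.
#'
#' @param r an [env_raster] or `class_map` (any object carrying
#'   `yllcorner`, `cellsize` and a cell matrix).
#' @return numeric vector, one area in km^2 per matrix row (north first).
#' @export
cell_area_km2 <- function(r) {
  m <- if (inherits(r, "class_map")) r$classes else r$values
  nr <- nrow(m)
  lat_top <- r$yllcorner + (nr:1) * r$cellsize
  lat_bot <- lat_top - r$cellsize
  if (any(abs(c(lat_top, lat_bot)) > 90 + 1e-9)) {
    stop("latitudes outside [-90, 90]")
  }
  R <- 6371.0088
  R^2 * (r$cellsize * pi / 180) * abs(sin(lat_top * pi / 180) -
                                        sin(lat_bot * pi / 180))
}

#' Ray-casting point-in-polygon test
#'
#' @param lon,lat point coordinates (vectors).
#' @param ring two-column polygon vertex matrix (closed or open ring).
#' @return logical vector; boundary behaviour follows the even-odd rule.
#' @export
point_in_polygon <- function(lon, lat, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  inside <- logical(length(lon))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((y[i] > lat) != (y[j] > lat)) &
      (lon < (x[j] - x[i]) * (lat - y[i]) / (y[j] - y[i]) + x[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# assign each valid cell center to the first region containing it;
# returns integer vector (NA = unassigned) over all cells in matrix order
assign_cells_to_regions <- function(cm, regions) {
  co <- raster_coords(classmap_raster(cm))
  assign <- rep(NA_integer_, nrow(co))
  multi <- FALSE
  for (k in seq_along(regions$id)) {
    hit <- point_in_polygon(co$lon, co$lat, regions$polygons[[k]])
    multi <- multi || any(hit & !is.na(assign))
    assign[hit & is.na(assign)] <- k
  }
  if (multi) warning("overlapping regions; cells assigned to the first match")
  assign
}

#' Per-region, per-class area summary
#'
#' Each cell is assigned to the region containing its center (first match
#' on overlap, with a warning); class areas in km^2 are summed per region.
#'
#' @param cm a `class_map` from [classify_suitability()].
#' @param regions a [region_set].
#' @return data frame of class `region_area_summary` with columns
#'   `region_id`, `class`, `area_km2`; attribute `class_totals` holds the
#'   per-class totals over all assigned cells.
#' @export
regional_summary <- function(cm, regions) {
  stopifnot(inherits(cm, "class_map"), inherits(regions, "region_set"))
  if (length(regions$id) == 0) stop("empty region set")
  assign <- assign_cells_to_regions(cm, regions)
  area_row <- cell_area_km2(cm)
  nr <- nrow(cm$classes)
  cell_area <- rep(area_row, times = ncol(cm$classes))  # column-major order
  cl <- as.vector(cm$classes)
  out <- expand.grid(region_id = regions$id, class = cm$labels,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$area_km2 <- 0
  ok <- !is.na(assign) & !is.na(cl)
  if (any(ok)) {
    agg <- tapply(cell_area[ok],
                  list(factor(regions$id[assign[ok]], levels = regions$id),
                       factor(cm$labels[cl[ok]], levels = cm$labels)),
                  sum)
    agg[is.na(agg)] <- 0
    out$area_km2 <- agg[cbind(match(out$region_id, regions$id),
                              match(out$class, cm$labels))]
  }
  tot <- tapply(out$area_km2, factor(out$class, levels = cm$labels), sum)
  attr(out, "class_totals") <- tot
  class(out) <- c("region_area_summary", class(out))
  out
}

#' Per-class share of total classified area
#'
#' @param summary a `region_area_summary` (or any data frame with `class`
#'   and `area_km2`).
#' @return named vector of percentages summing to 100.
#' @export
area_shares <- function(summary) {
  tot <- tapply(summary$area_km2, factor(summary$class,
                                         levels = unique(summary$class)), sum)
  stats::setNames(as.numeric(100 * tot / sum(tot)), names(tot))
}

#' Area-weighted centroid of suitability classes
#'
#' @param cm a `class_map`.
#' @param classes labels (or integer codes) of the classes to include.
#' @return named vector `c(lon, lat)`.
#' @export
class_centroid <- function(cm, classes) {
  if (is.character(classes)) classes <- match(classes, cm$labels)
  sel <- !is.na(cm$classes) & (cm$classes %in% classes)
  if (!any(sel)) stop("selected class is empty")
  co <- raster_coords(classmap_raster(cm))
  w <- rep(cell_area_km2(cm), times = ncol(cm$classes))[as.vector(sel)]
  c(lon = stats::weighted.mean(co$lon[as.vector(sel)], w),
    lat = stats::weighted.mean(co$lat[as.vector(sel)], w))
}

#' Great-circle distance and bearing between two centroids
#'
#' Haversine distance on a sphere of radius 6371.0088 km; the initial
#' bearing is reported both in degrees and as one of eight compass
#' sectors ("northward", "northeastward", ...).
#'
#' @param c1,c2 vectors `c(lon, lat)` in degrees.
#' @return list of class `centroid_shift`: `distance_km`, `bearing_deg`,
#'   `direction`, `from`, `to`.
#' @export
centroid_shift <- function(c1, c2) {
  to_rad <- pi / 180
  lat1 <- c1[[2]] * to_rad; lat2 <- c2[[2]] * to_rad
  dlat <- (c2[[2]] - c1[[2]]) * to_rad
  dlon <- (c2[[1]] - c1[[1]]) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1) * cos(lat2) * sin(dlon / 2)^2
  d <- 2 * 6371.0088 * asin(pmin(1, sqrt(a)))
  brg <- atan2(sin(dlon) * cos(lat2),
               cos(lat1) * sin(lat2) - sin(lat1) * cos(lat2) * cos(dlon))
  brg <- (brg / to_rad) %% 360
  dirs <- c("northward", "northeastward", "eastward", "southeastward",
            "southward", "southwestward", "westward", "northwestward")
  direction <- if (d == 0) "none" else dirs[(floor((brg + 22.5) / 45) %% 8) + 1]
  structure(list(distance_km = d, bearing_deg = brg, direction = direction,
                 from = c(lon = c1[[1]], lat = c1[[2]]),
                 to = c(lon = c2[[1]], lat = c2[[2]])),
            class = "centroid_shift")
}

#' @export
#' @method print centroid_shift
print.centroid_shift <- function(x, ...) {
  cat(sprintf("<centroid_shift> %.2f km %s (bearing %.1f deg)\n",
              x$distance_km, x$direction, x$bearing_deg))
  invisible(x)
}

#' Period-to-period change in class areas
#'
#' @param summary_t1,summary_t2 `region_area_summary` objects on the same
#'   class scheme (period 1 and period 2).
#' @return data frame with per-class areas `area_t1`/`area_t2` (km^2),
#'   `change_km2` and `change_pct` (`100 * (A2 - A1) / A1`; `NA` where
#'   `A1 = 0`).
#' @export
change_summary <- function(summary_t1, summary_t2) {
  cls <- unique(as.character(summary_t1$class))
  if (!identical(cls, unique(as.character(summary_t2$class)))) {
    stop("summaries use different class schemes")
  }
  a1 <- tapply(summary_t1$area_km2, factor(summary_t1$class, levels = cls), sum)
  a2 <- tapply(summary_t2$area_km2, factor(summary_t2$class, levels = cls), sum)
  pct <- ifelse(a1 == 0, NA_real_, 100 * (a2 - a1) / a1)
  data.frame(class = cls, area_t1 = as.vector(a1), area_t2 = as.vector(a2),
             change_km2 = as.vector(a2 - a1), change_pct = as.vector(pct),
             stringsAsFactors = FALSE)
}
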