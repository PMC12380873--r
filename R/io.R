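#' Read an ESRI ASCII grid
#'
#' Parses the standard six-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`; the nodata line is optional)
#' followed by whitespace-separated cell values, north row first.
#'
#' @param path file path.
#' @return an [env_raster]; nodata cells are `NA`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 0L
  while (i < length(lines)) {
    tok <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(tok) == 2 && grepl("^[A-Za-z_]", tok[1])) {
      val <- suppressWarnings(as.numeric(tok[2]))
      if (is.na(val)) stop(sprintf("malformed header at line %d of %s", i + 1L, path))
      hdr[[tolower(tok[1])]] <- val
      i <- i + 1L
    } else break
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(req, names(hdr))
  if (length(miss)) {
    stop(sprintf("malformed ESRI ASCII header in %s: missing %s (line %d)",
                 path, paste(miss, collapse = ", "), i + 1L))
  }
  vals <- scan(text = paste(lines[(i + 1L):length(lines)], collapse = "\n"),
               what = numeric(), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop(sprintf("%s: expected %d values, found %d", path, nr * nc, length(vals)))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  env_raster(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize)
}

#' Write an ESRI ASCII grid
#'
#' Values are written with 17 significant digits so a write/read round trip
#' is bit-exact for doubles.
#'
#' @param r an [env_raster].
#' @param path output path.
#' @param nodata value standing in for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  stopifnot(inherits(r, "env_raster"))
  m <- r$values
  m[is.na(m)] <- nodata
  num <- function(v) formatC(v, digits = 17, format = "g")
  hdr <- c(
    paste("ncols", ncol(m)), paste("nrows", nrow(m)),
    paste("xllcorner", num(r$xllcorner)), paste("yllcorner", num(r$yllcorner)),
    paste("cellsize", num(r$cellsize)), paste("NODATA_value", num(nodata))
  )
  body <- apply(m, 1, function(row) paste(num(row), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read and write region polygons as GeoJSON
#'
#' Regions are a GeoJSON FeatureCollection of Polygon features with an
#' `id` property.  Only single-ring polygons are supported.
#'
#' @param regions a [region_set].
#' @param path file path.
#' @return `read_regions_geojson`: a `region_set`; `write_regions_geojson`:
#'   `path`, invisibly.
#' @export
write_regions_geojson <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  feats <- lapply(seq_along(regions$id), function(i) {
    ring <- regions$polygons[[i]]
    list(
      type = "Feature",
      properties = list(id = regions$id[i]),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(j) ring[j, ]))
      )
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_regions_geojson
#' @export
read_regions_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  if (is.null(g$type) || g$type != "FeatureCollection") {
    stop("not a GeoJSON FeatureCollection: ", path)
  }
  ids <- character(0); polys <- list()
  for (f in g$features) {
    if (f$geometry$type != "Polygon") stop("only Polygon features are supported")
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    ids <- c(ids, as.character(f$properties$id))
    polys <- c(polys, list(unname(ring)))
  }
  region_set(ids, polys)
}

#' Read and write trait tables as CSV
#'
#' The on-disk dialect is one replicate measurement per row with columns
#' `germplasm_id`, `trait`, `replicate`, `value`, `fertility_completed`.
#'
#' @param table a trait table data frame.
#' @param path file path.
#' @return `read_trait_csv`: the trait table data frame.
#' @export
write_trait_csv <- function(table, path) {
  stopifnot(all(c("germplasm_id", "trait", "replicate", "value",
                  "fertility_completed") %in% names(table)))
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trait_csv
#' @export
read_trait_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("germplasm_id", "trait", "replicate", "value", "fertility_completed")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("trait CSV missing columns: ", paste(miss, collapse = ", "))
  tab$fertility_completed <- as.logical(tab$fertility_completed)
  tab
}

#' Read a pipeline configuration file
#'
#' JSON is the native format; `.yaml`/`.yml` is accepted when the yaml
#' package is installed.
#'
#' @param path file path.
#' @return a nested list of configuration values.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package; use JSON instead")
    }
    return(yaml::read_yaml(path))
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}
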