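#' Standard oat agronomic trait set
#'
#' The 23 agronomic trait abbreviations used throughout the package, with
#' default per-trait baselines (roughly field-realistic magnitudes), scales
#' linking each trait to the latent yield potential, orientations
#' (benefit/cost) and signs of the trait-yield association.  Thousand
#' kernel weight (TKW) and seed width (SW) act against forage yield and
#' are treated as cost traits; hay/fresh ratio (HFR), seed length (SL),
#' leaf layers (RL) and fertile tillers (NFT) are yield-neutral.
#'
#' @return data frame with columns `trait`, `baseline`, `scale`, `sign`,
#'   `orientation`.
#' @export
default_traits <- function() {
  tr <- c("HFR", "PH", "RD", "SL", "RL", "SW", "LLf", "SLR", "LWf", "TSI",
          "LLfs", "LWfs", "SPL", "HYL", "TKW", "HY", "FY", "LAf", "HYS",
          "NTT", "LAfs", "NFT", "NVT")
  baseline <- c(HFR = 0.30, PH = 133, RD = 9.9, SL = 16.8, RL = 7.5,
                SW = 3.1, LLf = 29, SLR = 1.5, LWf = 2.6, TSI = 6.3,
                LLfs = 39.5, LWfs = 2.6, SPL = 30.8, HYL = 48.5, TKW = 25.3,
                HY = 122, FY = 417, LAf = 64.8, HYS = 73.9, NTT = 20.2,
                LAfs = 87.8, NFT = 11.5, NVT = 8.6)
  sign <- c(HFR = 0, PH = 1, RD = 1, SL = 0, RL = 0, SW = -1, LLf = 1,
            SLR = 1, LWf = 1, TSI = 1, LLfs = 1, LWfs = 1, SPL = 1,
            HYL = 1, TKW = -1, HY = 1, FY = 1, LAf = 1, HYS = 1, NTT = 1,
            LAfs = 1, NFT = 0, NVT = 1)
  data.frame(
    trait = tr,
    baseline = unname(baseline[tr]),
    # per-trait units per unit of latent yield potential: ~4% of baseline,
    # giving between-germplasm CVs in the observed 10-30% range at the
    # default germplasm_sd of 5
    scale = unname(baseline[tr]) * 0.04,
    sign = unname(sign[tr]),
    orientation = ifelse(sign[tr] < 0, "cost", "benefit"),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the trait-table simulator
#'
#' The defaults emulate the field design this package targets: 62
#' germplasms, 23 agronomic traits, each measurement repeated on 10
#' plants, with 19/62 germplasms failing to complete the fertility period.
#'
#' @param n_germplasm,n_traits,n_reps design counts (`n_reps >= 2`).
#' @param effect_signs named numeric vector in `{-1, 0, 1}` linking each
#'   trait to the latent yield potential; defaults from [default_traits()].
#' @param germplasm_sd sd of the latent yield potential across germplasms.
#' @param replicate_sd replicate noise, expressed per unit of each trait's
#'   scale so `germplasm_sd / replicate_sd` is the signal-to-noise ratio
#'   for every trait.
#' @param fertility_fail_fraction fraction of germplasms flagged as not
#'   completing fertility, in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return an object of class `trait_sim_config`.
#' @export
trait_sim_config <- function(n_germplasm = 62, n_traits = 23, n_reps = 10,
                             effect_signs = NULL, germplasm_sd = 5,
                             replicate_sd = 1,
                             fertility_fail_fraction = 19 / 62, seed = 1) {
  if (n_germplasm < 1 || n_traits < 1) stop("counts must be positive")
  if (n_reps < 2) stop("n_reps must be >= 2")
  if (germplasm_sd <= 0 || replicate_sd <= 0) stop("sds must be > 0")
  if (fertility_fail_fraction < 0 || fertility_fail_fraction >= 1) {
    stop("fertility_fail_fraction must be in [0, 1)")
  }
  def <- default_traits()
  if (n_traits <= nrow(def)) {
    def <- def[seq_len(n_traits), ]
  } else {
    extra <- (nrow(def) + 1):n_traits
    def <- rbind(def, data.frame(
      trait = sprintf("X%02d", extra), baseline = 10, scale = 0.4,
      sign = 1, orientation = "benefit"
    ))
  }
  if (!is.null(effect_signs)) {
    stopifnot(!is.null(names(effect_signs)),
              all(names(effect_signs) %in% def$trait),
              all(effect_signs %in% c(-1, 0, 1)))
    def$sign[match(names(effect_signs), def$trait)] <- unname(effect_signs)
    def$orientation <- ifelse(def$sign < 0, "cost", "benefit")
  }
  structure(list(n_germplasm = n_germplasm, n_traits = n_traits,
                 n_reps = n_reps, traits = def, germplasm_sd = germplasm_sd,
                 replicate_sd = replicate_sd,
                 fertility_fail_fraction = fertility_fail_fraction,
                 seed = seed),
            class = "trait_sim_config")
}

#' Simulate a germplasm-by-trait replicate table with known ground truth
#'
#' Each germplasm g carries a latent yield potential `latent_g ~
#' N(0, germplasm_sd)`.  The replicate value of trait t is
#' `baseline_t + sign_t * latent_g * scale_t + N(0, replicate_sd * scale_t)`,
#' truncated below at 0 for non-negative traits.  A fixed number of
#' germplasms (`round(fertility_fail_fraction * n)`) is flagged as not
#' having completed the fertility period; they remain in the table so
#' filtering is an explicit downstream step.
#'
#' @param cfg a [trait_sim_config].
#' @return list of class `trait_sim` with elements `table` (long data
#'   frame: `germplasm_id`, `trait`, `replicate`, `value`,
#'   `fertility_completed`), `latent` (named vector, the ground-truth
#'   yield potential), `traits` (the trait definition used) and `config`.
#' @export
generate_trait_table <- function(cfg) {
  stopifnot(inherits(cfg, "trait_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_germplasm
  ids <- sprintf("AS%02d", seq_len(n))
  latent <- stats::setNames(stats::rnorm(n, 0, cfg$germplasm_sd), ids)
  n_fail <- round(cfg$fertility_fail_fraction * n)
  failed <- sample(ids, n_fail)
  tr <- cfg$traits
  rows <- vector("list", n)
  for (g in seq_len(n)) {
    mu <- tr$baseline + tr$sign * latent[g] * tr$scale
    vals <- mu + stats::rnorm(nrow(tr) * cfg$n_reps, 0,
                              cfg$replicate_sd * tr$scale)
    vals <- pmax(matrix(vals, nrow = nrow(tr)), 0)
    rows[[g]] <- data.frame(
      germplasm_id = ids[g],
      trait = rep(tr$trait, times = cfg$n_reps),
      replicate = rep(seq_len(cfg$n_reps), each = nrow(tr)),
      value = as.vector(vals),
      fertility_completed = !(ids[g] %in% failed),
      stringsAsFactors = FALSE
    )
  }
  structure(list(table = do.call(rbind, rows), latent = latent,
                 traits = tr, config = cfg),
            class = "trait_sim")
}

#' Configuration for the synthetic landscape simulator
#'
#' @param extent named numeric vector `c(xmin, xmax, ymin, ymax)`, degrees.
#' @param resolution cell size in degrees (default 1/12, i.e. 5 arc-min).
#' @param n_layers number of environmental layers (>= 3).
#' @param smoothness positive; larger values give smoother fields.
#' @param n_presence default presence count for [generate_occurrences()].
#' @param true_coefficients named vector of logistic coefficients over (a
#'   subset of) the layer names; unnamed vectors apply to the first layers.
#' @param intercept logistic intercept of the true suitability function.
#' @param seed integer RNG seed.
#' @return an object of class `landscape_sim_config`.
#' @export
landscape_sim_config <- function(extent = c(xmin = 88, xmax = 105,
                                            ymin = 26, ymax = 39),
                                 resolution = 1 / 12, n_layers = 6,
                                 smoothness = 2, n_presence = 500,
                                 true_coefficients = c(2.5, -1.8),
                                 intercept = -0.5, seed = 1) {
  extent <- unname(extent[c("xmin", "xmax", "ymin", "ymax")])
  if (anyNA(extent)) extent <- unname(extent)
  if (length(extent) != 4 || extent[1] >= extent[2] || extent[3] >= extent[4]) {
    stop("degenerate extent: need xmin < xmax and ymin < ymax")
  }
  if (resolution <= 0) stop("resolution must be > 0")
  if (n_layers < 3) stop("n_layers must be >= 3")
  if (smoothness <= 0) stop("smoothness must be > 0")
  structure(list(extent = stats::setNames(extent, c("xmin", "xmax", "ymin", "ymax")),
                 resolution = resolution, n_layers = n_layers,
                 smoothness = smoothness, n_presence = n_presence,
                 true_coefficients = true_coefficients,
                 intercept = intercept, seed = seed),
            class = "landscape_sim_config")
}

# one smooth random field on the unit square: low-frequency sinusoids plus
# box-smoothed white noise whose weight shrinks with smoothness
random_field <- function(nr, nc, smoothness) {
  u <- matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr, nc)
  v <- matrix(rep((seq_len(nr) - 0.5) / nr, times = nc), nr, nc)
  f <- matrix(0, nr, nc)
  for (h in 1:4) {
    amp <- stats::rnorm(1)
    fx <- stats::runif(1, -1.5, 1.5) / smoothness
    fy <- stats::runif(1, -1.5, 1.5) / smoothness
    ph <- stats::runif(1, 0, 2 * pi)
    f <- f + amp * sin(2 * pi * (fx * u * nc / 10 + fy * v * nr / 10) + ph)
  }
  eps <- matrix(stats::rnorm(nr * nc), nr, nc)
  sm <- eps
  if (nr >= 3 && nc >= 3) {
    # plus-shaped smoothing kernel with edge replication
    sm <- (eps +
             rbind(eps[-1, ], eps[nr, ]) + rbind(eps[1, ], eps[-nr, ]) +
             cbind(eps[, -1], eps[, nc]) + cbind(eps[, 1], eps[, -nc])) / 5
  }
  f <- f + sm * (0.2 / smoothness)
  (f - mean(f)) / stats::sd(as.vector(f))
}

#' Simulate an environmental stack with a known suitability truth
#'
#' Generates `n_layers` smooth random fields on a shared grid and defines
#' the true suitability as `plogis(intercept + sum coef_l * layer_l)` over
#' the coefficient-bearing layers.  Fully seeded and deterministic.
#'
#' @param cfg a [landscape_sim_config].
#' @return list of class `landscape_sim` with `stack` (an [env_stack],
#'   layers `bio01`, `bio02`, ...), `truth` (an [env_raster] of true
#'   suitability in `[0, 1]`) and `config`.
#' @export
generate_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "landscape_sim_config"))
  set.seed(cfg$seed)
  e <- cfg$extent
  nc <- max(1L, round((e["xmax"] - e["xmin"]) / cfg$resolution))
  nr <- max(1L, round((e["ymax"] - e["ymin"]) / cfg$resolution))
  lnames <- sprintf("bio%02d", seq_len(cfg$n_layers))
  layers <- lapply(lnames, function(nm) {
    env_raster(random_field(nr, nc, cfg$smoothness),
               unname(e["xmin"]), unname(e["ymin"]), cfg$resolution)
  })
  names(layers) <- lnames
  stack <- env_stack(layers)
  cf <- cfg$true_coefficients
  if (is.null(names(cf))) names(cf) <- lnames[seq_along(cf)]
  stopifnot(all(names(cf) %in% lnames))
  eta <- matrix(cfg$intercept, nr, nc)
  for (nm in names(cf)) eta <- eta + cf[[nm]] * layers[[nm]]$values
  truth <- env_raster(stats::plogis(eta), unname(e["xmin"]), unname(e["ymin"]),
                      cfg$resolution)
  structure(list(stack = stack, truth = truth, config = cfg),
            class = "landscape_sim")
}

#' Sample presence points from a suitability truth
#'
#' Cells are sampled with probability proportional to true suitability;
#' each sampled cell contributes its center as one lon/lat point.
#'
#' @param truth an [env_raster] with values in `[0, 1]`.
#' @param n_presence number of points.
#' @param seed integer RNG seed.
#' @param allow_duplicates sample cells with replacement.
#' @return data frame with columns `lon`, `lat`.
#' @export
generate_occurrences <- function(truth, n_presence, seed = 1,
                                 allow_duplicates = FALSE) {
  stopifnot(inherits(truth, "env_raster"))
  p <- as.vector(truth$values)
  if (any(p < -1e-12 | p > 1 + 1e-12, na.rm = TRUE)) {
    stop("truth must lie in [0, 1]")
  }
  p[is.na(p)] <- 0
  pos <- sum(p > 0)
  if (!allow_duplicates && n_presence > pos) {
    stop(sprintf("n_presence (%d) exceeds the %d cells with positive suitability",
                 n_presence, pos))
  }
  set.seed(seed)
  idx <- sample.int(length(p), n_presence, replace = allow_duplicates, prob = p)
  co <- raster_coords(truth)
  data.frame(lon = co$lon[idx], lat = co$lat[idx])
}

#' Named region polygons
#'
#' @param id character vector of region ids.
#' @param polygons list of closed rings (two-column lon/lat matrices; the
#'   first and last vertex may coincide but need not).
#' @return an object of class `region_set`.
#' @export
region_set <- function(id, polygons) {
  stopifnot(length(id) == length(polygons), !anyDuplicated(id))
  structure(list(id = as.character(id), polygons = polygons),
            class = "region_set")
}

#' @export
#' @method print region_set
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %d regions: %s%s\n", length(x$id),
              paste(utils::head(x$id, 6), collapse = ", "),
              if (length(x$id) > 6) ", ..." else ""))
  invisible(x)
}

#' @export
length.region_set <- function(x) length(x$id)

#' Tile an extent with a rectangular grid of mock administrative regions
#'
#' @param extent named vector `c(xmin, xmax, ymin, ymax)`, degrees.
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @return a [region_set] with ids `SP01`, `SP02`, ... in row-major order
#'   from the south-west corner.
#' @export
generate_regions <- function(extent, n_rows, n_cols) {
  if (n_rows < 1 || n_cols < 1) stop("n_rows and n_cols must be >= 1")
  e <- extent[c("xmin", "xmax", "ymin", "ymax")]
  if (anyNA(e)) e <- stats::setNames(unname(extent)[1:4], c("xmin", "xmax", "ymin", "ymax"))
  dx <- (e[["xmax"]] - e[["xmin"]]) / n_cols
  dy <- (e[["ymax"]] - e[["ymin"]]) / n_rows
  polys <- list(); ids <- character(0); k <- 0L
  for (i in seq_len(n_rows)) {
    for (j in seq_len(n_cols)) {
      k <- k + 1L
      x0 <- e[["xmin"]] + (j - 1) * dx; y0 <- e[["ymin"]] + (i - 1) * dy
      polys[[k]] <- cbind(c(x0, x0 + dx, x0 + dx, x0, x0),
                          c(y0, y0, y0 + dy, y0 + dy, y0))
      ids[k] <- sprintf("SP%02d", k)
    }
  }
  region_set(ids, polys)
}

#' Polygon area in squared degrees (planar shoelace formula)
#'
#' Used for the tiling/partition checks of synthetic regions; not an
#' area on the sphere (see [cell_area_km2()] for that).
#'
#' @param ring two-column vertex matrix.
#' @return non-negative area.
#' @export
ring_area_deg2 <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  if (x[1] != x[n] || y[1] != y[n]) { x <- c(x, x[1]); y <- c(y, y[1]) }
  abs(sum(x[-length(x)] * y[-1] - x[-1] * y[-length(y)])) / 2
}
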