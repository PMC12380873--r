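#' Zonal environmental and suitability profiles per region
#'
#' Cell-center zonal statistics: per region, the mean and median consensus
#' suitability, the mean of each environmental layer, and (when a class
#' map is supplied) the suitable area in km^2 (all classes above the
#' lowest).  Regions containing no cell centers are dropped with a
#' warning.
#'
#' @param suitability an [env_raster] with values in `[0, 1]`.
#' @param stack an [env_stack] on the same grid.
#' @param regions a [region_set].
#' @param classmap optional `class_map` for suitable-area accounting.
#' @return data frame of class `region_profiles`: `region_id`, `n_cells`,
#'   `suit_mean`, `suit_median`, `suitable_area_km2`, one `env_<layer>`
#'   column per layer.
#' @export
region_profiles <- function(suitability, stack, regions, classmap = NULL) {
  stopifnot(inherits(suitability, "env_raster"), inherits(stack, "env_stack"),
            inherits(regions, "region_set"))
  if (length(regions$id) == 0) stop("empty region set")
  if (!same_grid(suitability, stack$layers[[1]])) {
    stop("suitability and stack must share one grid")
  }
  cm_like <- structure(list(classes = suitability$values,
                            xllcorner = suitability$xllcorner,
                            yllcorner = suitability$yllcorner,
                            cellsize = suitability$cellsize),
                       class = "class_map")
  assign <- assign_cells_to_regions(cm_like, regions)
  suit <- as.vector(suitability$values)
  env <- vapply(stack$layers, function(l) as.vector(l$values),
                numeric(length(suit)))
  area <- rep(cell_area_km2(suitability), times = ncol(suitability$values))
  suitable <- if (!is.null(classmap)) as.vector(classmap$classes) > 1 else NULL
  rows <- lapply(seq_along(regions$id), function(k) {
    ix <- which(assign == k & !is.na(suit))
    if (length(ix) == 0) return(NULL)
    prof <- data.frame(region_id = regions$id[k], n_cells = length(ix),
                       suit_mean = mean(suit[ix]),
                       suit_median = stats::median(suit[ix]),
                       suitable_area_km2 = if (is.null(suitable)) NA_real_ else
                         sum(area[ix][suitable[ix] %in% TRUE]),
                       stringsAsFactors = FALSE)
    for (nm in colnames(env)) prof[[paste0("env_", nm)]] <- mean(env[ix, nm])
    prof
  })
  empty <- vapply(rows, is.null, logical(1))
  if (any(empty)) {
    warning("dropping regions with no cells: ",
            paste(regions$id[empty], collapse = ", "))
  }
  out <- do.call(rbind, rows[!empty])
  if (is.null(out)) stop("no region contains any valid cell")
  class(out) <- c("region_profiles", class(out))
  out
}

profile_features <- function(profiles) {
  fx <- as.matrix(profiles[, grep("^env_", names(profiles)), drop = FALSE])
  rownames(fx) <- profiles$region_id
  fx
}

dissimilarity_matrix <- function(x, method) {
  x <- as.matrix(x)
  switch(method,
    euclidean = as.matrix(stats::dist(x, method = "euclidean")),
    manhattan = as.matrix(stats::dist(x, method = "manhattan")),
    bray = {
      if (any(x < 0)) stop("bray-curtis requires non-negative features")
      n <- nrow(x)
      d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (j > i) {
          denom <- sum(x[i, ] + x[j, ])
          d[i, j] <- d[j, i] <- if (denom == 0) 0 else
            sum(abs(x[i, ] - x[j, ])) / denom
        }
      }
      d
    },
    gower = {
      rng <- apply(x, 2, function(v) diff(range(v)))
      rng[rng == 0] <- 1
      xs <- sweep(x, 2, rng, "/")
      as.matrix(stats::dist(xs, method = "manhattan")) / ncol(x)
    },
    stop("unknown dissimilarity: ", method)
  )
}

#' Screen candidate dissimilarity indices against suitability structure
#'
#' For each candidate index, computes the Spearman rank correlation
#' between the pairwise region dissimilarities of the environmental
#' profile features and the pairwise absolute differences in region mean
#' suitability, then picks the candidate with the largest correlation
#' (ties broken by candidate order).
#'
#' @param profiles a `region_profiles` data frame (>= 4 regions).
#' @param candidates character vector of index names among `"euclidean"`,
#'   `"manhattan"`, `"bray"`, `"gower"`.
#' @return list with `chosen`, `rank_correlation` (named vector) and
#'   `dissimilarity` (matrix of the chosen index).
#' @export
optimal_dissimilarity <- function(profiles,
                                  candidates = c("euclidean", "manhattan",
                                                 "bray", "gower")) {
  if (nrow(profiles) < 4) stop("need >= 4 regions")
  fx <- profile_features(profiles)
  if (all(apply(fx, 2, function(v) diff(range(v)) == 0))) {
    stop("constant profiles: no dissimilarity structure to screen")
  }
  target <- as.matrix(stats::dist(profiles$suit_mean, method = "manhattan"))
  lt <- lower.tri(target)
  rc <- vapply(candidates, function(m) {
    # candidates not defined on these features (e.g. bray-curtis on signed
    # values) are screened out rather than failing the whole search
    tryCatch({
      d <- dissimilarity_matrix(fx, m)
      suppressWarnings(stats::cor(d[lt], target[lt], method = "spearman"))
    }, error = function(e) NA_real_)
  }, numeric(1))
  rc[is.na(rc)] <- -Inf
  chosen <- candidates[which.max(rc)]  # which.max takes the first maximum
  rc[!is.finite(rc)] <- NA_real_
  list(chosen = chosen, rank_correlation = rc,
       dissimilarity = dissimilarity_matrix(fx, chosen))
}

#' Mantel permutation test between two distance matrices
#'
#' The statistic is the (Spearman by default) correlation of the
#' off-diagonal upper-triangle entries; the null distribution permutes the
#' rows and columns of `d2` simultaneously.  When `n! <= 720` (n <= 6)
#' and `exact` is not `FALSE`, all permutations are enumerated and the
#' p-value is exact; otherwise `permutations` random permutations give
#' `p = (1 + #{perm >= observed}) / (permutations + 1)`.
#'
#' @param d1,d2 symmetric zero-diagonal matrices of equal size (n >= 4).
#' @param method `"spearman"` or `"pearson"`.
#' @param permutations number of random permutations (sampling mode).
#' @param seed integer RNG seed (sampling mode).
#' @param exact force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   `NULL` decides by `n! <= 720`.
#' @return object of class `mantel_result`: `statistic`, `p_value`,
#'   `permutations`, `exact`, `method`, `seed`.
#' @export
mantel_test <- function(d1, d2, method = c("spearman", "pearson"),
                        permutations = 999, seed = 1, exact = NULL) {
  method <- match.arg(method)
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  n <- nrow(d1)
  check_dist <- function(d, nm) {
    if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)) ||
        any(abs(diag(d)) > 1e-12)) {
      stop(nm, " must be symmetric with zero diagonal")
    }
  }
  check_dist(d1, "d1"); check_dist(d2, "d2")
  if (n < 4 || nrow(d2) != n) stop("need matching matrices with n >= 4")
  ut <- upper.tri(d1)
  stat_fun <- function(perm) {
    suppressWarnings(stats::cor(d1[ut], d2[perm, perm][ut], method = method))
  }
  obs <- stat_fun(seq_len(n))
  do_exact <- if (is.null(exact)) factorial(n) <= 720 else isTRUE(exact)
  if (do_exact) {
    perms <- all_permutations(n)
    stats_ <- vapply(perms, stat_fun, numeric(1))
    p <- mean(stats_ >= obs - 1e-12)
    np <- length(perms)
  } else {
    set.seed(seed)
    stats_ <- vapply(seq_len(permutations),
                     function(i) stat_fun(sample.int(n)), numeric(1))
    p <- (1 + sum(stats_ >= obs - 1e-12)) / (permutations + 1)
    np <- permutations
  }
  structure(list(statistic = obs, p_value = p, permutations = np,
                 exact = do_exact, method = method, seed = seed),
            class = "mantel_result")
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' @export
#' @method print mantel_result
print.mantel_result <- function(x, ...) {
  cat(sprintf("<mantel_result> r = %.4f (%s), p = %.4g (%s, %d permutations)\n",
              x$statistic, x$method, x$p_value,
              if (x$exact) "exact" else "sampled", x$permutations))
  invisible(x)
}

#' Region-by-region environmental similarity (Spearman)
#'
#' @param profiles a `region_profiles` data frame.
#' @return symmetric matrix of Spearman correlations between the regions'
#'   environmental feature vectors.
#' @export
region_similarity_matrix <- function(profiles) {
  fx <- profile_features(profiles)
  suppressWarnings(stats::cor(t(fx), method = "spearman"))
}

#' Environmental profile of a trial site
#'
#' @param stack an [env_stack].
#' @param lon,lat trial-site coordinates.
#' @return named feature vector (`env_<layer>`) at the containing cell.
#' @export
trial_site_profile <- function(stack, lon, lat) {
  v <- extract_env(stack, data.frame(lon = lon, lat = lat))[1, ]
  if (anyNA(v)) stop("trial site falls on nodata or outside the extent")
  stats::setNames(as.vector(v), paste0("env_", names(stack$layers)))
}

#' Germplasm-by-region introduction adaptability matrix
#'
#' Combines three ingredients: the germplasm's comprehensive membership
#' score `M(g)` (computed on the entropy-weighted normalized trait
#' matrix), the region's mean suitability `S(r)` as the geographic
#' standard, and the environmental similarity `sim(r)` between the region
#' profile and the trial site (Spearman).  The score is the
#' similarity-gated product
#' `A(g, r) = M(g) * S(r) * (1 + sim(r)) / 2`, in `[0, 1]`, monotone in
#' each ingredient.  Per-region significance is a permutation p-value of
#' `sim(r)` under random reordering of the trial-site features; scores are
#' classified into none/low/high by Fisher-Jenks (k = 3) over all pairs.
#'
#' @param membership a `membership_result` (see [membership_scores()]).
#' @param profiles a `region_profiles` data frame.
#' @param trial_profile named feature vector from [trial_site_profile()].
#' @param permutations permutation count for the similarity null.
#' @param seed integer RNG seed.
#' @return object of class `adaptability_matrix`: `scores` (germplasm x
#'   region), `p_values` (per region), `similarity` (per region),
#'   `classes` (germplasm x region factor levels none/low/high),
#'   `suitable_area_km2` (per germplasm: total suitable area over regions
#'   with adaptability above "none"), `region_similarity` (region x
#'   region Spearman matrix).
#' @export
adaptability_matrix <- function(membership, profiles, trial_profile,
                                permutations = 199, seed = 1) {
  stopifnot(inherits(membership, "membership_result"))
  fx <- profile_features(profiles)
  if (!identical(sort(colnames(fx)), sort(names(trial_profile)))) {
    stop("profiles and trial_profile use different feature sets")
  }
  fx <- fx[, names(trial_profile), drop = FALSE]
  M <- membership$scores
  S <- stats::setNames(profiles$suit_mean, profiles$region_id)
  nfeat <- length(trial_profile)
  sim <- apply(fx, 1, function(v)
    suppressWarnings(stats::cor(v, trial_profile, method = "spearman")))
  sim[is.na(sim)] <- 0
  set.seed(seed)
  p_values <- vapply(seq_len(nrow(fx)), function(r) {
    null <- vapply(seq_len(permutations), function(i) {
      s <- suppressWarnings(stats::cor(fx[r, ], trial_profile[sample.int(nfeat)],
                                       method = "spearman"))
      if (is.na(s)) 0 else s
    }, numeric(1))
    (1 + sum(null >= sim[r] - 1e-12)) / (permutations + 1)
  }, numeric(1))
  names(p_values) <- rownames(fx)
  A <- outer(M, S * (1 + pmax(sim, -1)) / 2)
  dimnames(A) <- list(names(M), profiles$region_id)
  vals <- as.vector(A)
  if (length(unique(vals)) >= 3) {
    br <- jenks_breaks(vals, k = 3)
    cl <- matrix(findInterval(A, br, left.open = TRUE) + 1L, nrow(A), ncol(A),
                 dimnames = dimnames(A))
  } else {
    warning("fewer than 3 distinct scores; all pairs classified 'low'")
    cl <- matrix(2L, nrow(A), ncol(A), dimnames = dimnames(A))
    br <- numeric(0)
  }
  labels <- c("none", "low", "high")
  sa <- stats::setNames(profiles$suitable_area_km2, profiles$region_id)
  suit_area <- apply(cl, 1, function(row) {
    ix <- which(row >= 2L)
    if (!length(ix) || all(is.na(sa))) 0 else sum(sa[ix], na.rm = TRUE)
  })
  structure(list(scores = A, p_values = p_values, similarity = sim,
                 classes = matrix(labels[cl], nrow(A), ncol(A),
                                  dimnames = dimnames(A)),
                 breaks = br, suitable_area_km2 = suit_area,
                 region_similarity = region_similarity_matrix(profiles)),
            class = "adaptability_matrix")
}

#' @export
#' @method print adaptability_matrix
print.adaptability_matrix <- function(x, ...) {
  cat(sprintf("<adaptability_matrix> %d germplasms x %d regions\n",
              nrow(x$scores), ncol(x$scores)))
  cat("class counts:\n")
  print(table(factor(x$classes, levels = c("none", "low", "high"))))
  invisible(x)
}
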