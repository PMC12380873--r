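#' Drop germplasms that did not complete the fertility period
#'
#' Late-maturing accessions that fail to finish their fertility period at a
#' cold-site trial are excluded before any performance analysis.
#'
#' @param table trait table (long format, see [read_trait_csv()]).
#' @return the filtered table; attribute `n_removed` holds the number of
#'   germplasms dropped.
#' @export
filter_fertility <- function(table) {
  stopifnot("fertility_completed" %in% names(table))
  ids <- unique(table$germplasm_id)
  keep <- table$fertility_completed
  out <- table[keep, , drop = FALSE]
  kept_ids <- unique(out$germplasm_id)
  if (length(kept_ids) == 0) stop("all germplasms failed fertility; nothing to analyse")
  n_removed <- length(ids) - length(kept_ids)
  message(sprintf("filter_fertility: removed %d of %d germplasms", n_removed,
                  length(ids)))
  attr(out, "n_removed") <- n_removed
  out
}

#' Descriptive statistics of a replicate vector
#'
#' Sample statistics as used in agronomic variation tables: min, max, mean,
#' sample (n-1) standard deviation and coefficient of variation in percent,
#' `cv = 100 * std / mean`.
#'
#' @param values numeric vector with at least two finite entries.
#' @return list with `min`, `max`, `mean`, `std`, `cv`.
#' @export
trait_describe <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need >= 2 finite values")
  m <- mean(values); s <- stats::sd(values)
  cv <- if (m == 0) {
    warning("mean is 0; CV undefined")
    NA_real_
  } else 100 * s / m
  list(min = min(values), max = max(values), mean = m, std = s, cv = cv)
}

#' Trait-level descriptive table
#'
#' One row per trait, statistics computed over germplasm means (not raw
#' replicates), mirroring the usual variation-analysis table layout.
#'
#' @param table trait table (long format), normally fertility-filtered.
#' @return data frame with columns `trait`, `min`, `max`, `mean`, `std`,
#'   `cv`, ordered by ascending `cv`.
#' @export
describe_traits <- function(table) {
  mt <- trait_means(table)
  out <- do.call(rbind, lapply(colnames(mt), function(tr) {
    d <- trait_describe(mt[, tr])
    data.frame(trait = tr, min = d$min, max = d$max, mean = d$mean,
               std = d$std, cv = d$cv, stringsAsFactors = FALSE)
  }))
  out[order(out$cv), , drop = FALSE]
}

#' Germplasm-by-trait matrix of replicate means
#'
#' @param table trait table (long format).
#' @return numeric matrix, rows = germplasms, columns = traits, preserving
#'   first-appearance order.
#' @export
trait_means <- function(table) {
  g <- factor(table$germplasm_id, levels = unique(table$germplasm_id))
  tr <- factor(table$trait, levels = unique(table$trait))
  tapply(table$value, list(g, tr), mean)
}

#' Corrected leaf area
#'
#' `area = length * width * R`, where R is the leaf-shape correction
#' coefficient (default 0.8317 for oat).
#'
#' @param length,width leaf dimensions in cm, non-negative.
#' @param R correction coefficient, > 0.
#' @return leaf area in cm^2.
#' @export
leaf_area <- function(length, width, R = 0.8317) {
  if (any(length < 0) || any(width < 0)) stop("length and width must be >= 0")
  if (R <= 0) stop("R must be > 0")
  length * width * R
}

#' Min-max normalization with trait orientation
#'
#' Benefit traits map to `(x - min) / (max - min)`, cost traits to
#' `(max - x) / (max - min)`, so 1 is always "better".  Constant columns
#' are set to 0 with a warning; the entropy weight of such a column is 0
#' downstream.
#'
#' @param mat germplasm x trait matrix (e.g. from [trait_means()]).
#' @param orientations named character vector, `"benefit"` or `"cost"` per
#'   column; unnamed columns default to benefit.
#' @return matrix of the same shape with entries in `[0, 1]`.
#' @export
min_max_normalize <- function(mat, orientations = NULL) {
  mat <- as.matrix(mat)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    rng <- range(x)
    if (rng[1] == rng[2]) {
      warning(sprintf("column %s is constant; normalized to 0",
                      colnames(mat)[j]))
      out[, j] <- 0
      next
    }
    ori <- "benefit"
    if (!is.null(orientations) && !is.null(colnames(mat))) {
      o <- orientations[colnames(mat)[j]]
      if (!is.na(o)) ori <- o
    }
    out[, j] <- if (identical(unname(ori), "cost")) {
      (rng[2] - x) / (rng[2] - rng[1])
    } else {
      (x - rng[1]) / (rng[2] - rng[1])
    }
  }
  out
}

#' Shannon trait diversity of a germplasm
#'
#' For each trait, the Shannon index over its replicate values,
#' `H_t = -sum p_i log(p_i)` with `p_i = value_i / sum(values)`; the
#' germplasm's trait diversity is the sum over traits.  With r equal
#' replicates every trait contributes `log(r)`, so the sum is bounded by
#' `n_traits * log(n_reps)`.
#'
#' @param block replicates x traits numeric matrix for one germplasm
#'   (non-negative values).
#' @return list with `total` (sum over traits) and `per_trait`.
#' @export
shannon_trait_diversity <- function(block) {
  block <- as.matrix(block)
  if (any(block < 0, na.rm = TRUE)) stop("values must be non-negative")
  per <- apply(block, 2, function(v) {
    s <- sum(v)
    if (s == 0) {
      warning("all-zero trait contributes 0 to Shannon diversity")
      return(0)
    }
    p <- v / s
    p <- p[p > 0]
    -sum(p * log(p))
  })
  list(total = sum(per), per_trait = per)
}

#' Shannon trait diversity for every germplasm in a table
#'
#' @param table trait table (long format).
#' @return named numeric vector of per-germplasm diversity sums.
#' @export
shannon_by_germplasm <- function(table) {
  ids <- unique(table$germplasm_id)
  vapply(ids, function(g) {
    sub <- table[table$germplasm_id == g, ]
    block <- tapply(sub$value, list(factor(sub$replicate),
                                    factor(sub$trait, levels = unique(sub$trait))),
                    mean)
    shannon_trait_diversity(block)$total
  }, numeric(1))
}

#' Pearson correlation matrix with two-tailed p-values
#'
#' p-values come from the t transform `t = r * sqrt((n-2)/(1-r^2))` with
#' n-2 degrees of freedom.  Zero-variance columns give `NA` rows/columns.
#'
#' @param mat germplasm x trait matrix (>= 3 rows).
#' @return list with `r` (correlations, unit diagonal) and `p`.
#' @export
pearson_matrix <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 3) stop("need >= 3 rows")
  sds <- apply(mat, 2, stats::sd)
  r <- suppressWarnings(stats::cor(mat))
  r[sds == 0, ] <- NA_real_; r[, sds == 0] <- NA_real_
  diag(r)[sds > 0] <- 1
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  diag(p)[sds > 0] <- 0
  list(r = r, p = p, n = n)
}
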