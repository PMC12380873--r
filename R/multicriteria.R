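#' Entropy weights over criteria
#'
#' Objective criterion weighting: each column's weight is proportional to
#' its information divergence `d_j = 1 - e_j`, where `e_j` is the
#' normalized Shannon entropy of the column's share distribution across
#' alternatives, `e_j = -(1/log n) * sum_i p_ij log p_ij` with
#' `p_ij = x_ij / sum_i x_ij` and `0 * log 0 := 0`.  Constant columns
#' (including all-zero columns) receive weight 0; if every column is
#' constant the weights fall back to uniform with a warning.
#'
#' @param mat n x m matrix with entries in `[0, 1]` (normally the min-max
#'   normalized trait matrix).
#' @return object of class `weight_vector`: list with `weights` (sums to
#'   1), `entropy`, `divergence`.
#' @export
entropy_weights <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < -1e-12 | mat > 1 + 1e-12, na.rm = TRUE)) {
    stop("entries must lie in [0, 1]; min-max normalize first")
  }
  n <- nrow(mat)
  e <- apply(mat, 2, function(x) {
    s <- sum(x)
    if (s == 0) return(1)  # zero column: no information, zero divergence
    p <- x / s
    p <- p[p > 0]
    -sum(p * log(p)) / log(n)
  })
  d <- 1 - e
  d[abs(d) < 1e-15] <- 0
  if (sum(d) == 0) {
    warning("all columns constant; falling back to uniform weights")
    w <- rep(1 / ncol(mat), ncol(mat))
  } else {
    w <- d / sum(d)
  }
  names(w) <- names(e) <- names(d) <- colnames(mat)
  structure(list(weights = w, entropy = e, divergence = d),
            class = "weight_vector")
}

#' @export
#' @method print weight_vector
print.weight_vector <- function(x, ...) {
  cat("<weight_vector>\n")
  print(round(x$weights, 4))
  invisible(x)
}

#' Grey relational analysis (Deng's relational degree)
#'
#' Ranks factor series by closeness to a reference series.  With
#' deviations `Delta_i(k) = |ref(k) - factor_i(k)|` and global minimum /
#' maximum deviation over all factors and observations, the relational
#' coefficient is `xi_i(k) = (Dmin + rho * Dmax) / (Delta_i(k) + rho *
#' Dmax)` and the relational degree `gamma_i` is the (optionally weighted)
#' mean of `xi_i(k)` over observations.  Inputs are expected on a
#' comparable scale, i.e. min-max normalized first.
#'
#' @param reference numeric n-vector (e.g. normalized yield).
#' @param factors n x m matrix of comparison series.
#' @param rho resolution coefficient in `(0, 1]`, default 0.5.
#' @param obs_weights optional observation weights (length n, summing to
#'   1); default uniform.  Supplying entropy weights over germplasms here
#'   reproduces the "entropy-weighted then grey correlation" workflow.
#' @return object of class `grey_result`: `gamma` (degrees in `(0, 1]`),
#'   `rank` (1 = most related), `xi`, `dmin`, `dmax`, `rho`.
#' @export
grey_relational <- function(reference, factors, rho = 0.5, obs_weights = NULL) {
  if (rho <= 0 || rho > 1) stop("rho must be in (0, 1]")
  factors <- as.matrix(factors)
  stopifnot(length(reference) == nrow(factors))
  n <- nrow(factors)
  w <- if (is.null(obs_weights)) rep(1 / n, n) else obs_weights / sum(obs_weights)
  stopifnot(length(w) == n)
  delta <- abs(factors - reference)
  dmin <- min(delta); dmax <- max(delta)
  if (dmax == 0) {
    warning("all series identical to the reference; all degrees are 1")
    xi <- matrix(1, n, ncol(factors), dimnames = dimnames(factors))
  } else {
    xi <- (dmin + rho * dmax) / (delta + rho * dmax)
  }
  gamma <- as.vector(crossprod(w, xi))
  names(gamma) <- colnames(factors)
  rk <- rank(-gamma, ties.method = "first")
  structure(list(gamma = gamma, rank = rk, xi = xi, dmin = dmin,
                 dmax = dmax, rho = rho),
            class = "grey_result")
}

#' @export
#' @method print grey_result
print.grey_result <- function(x, ...) {
  ord <- order(x$rank)
  cat(sprintf("<grey_result> rho = %g\n", x$rho))
  print(data.frame(factor = names(x$gamma)[ord],
                   relevance = round(x$gamma[ord], 3),
                   rank = x$rank[ord], row.names = NULL))
  invisible(x)
}

#' Grey relational table against one or more yield targets
#'
#' Convenience wrapper combining Pearson correlations and grey relational
#' degrees of every non-target trait against each yield target, the shape
#' of a classic "correlation / relevance / rank" table.
#'
#' @param mat germplasm x trait matrix of means.
#' @param targets character vector of target trait names (e.g. `c("HY",
#'   "FY")`).
#' @param rho resolution coefficient.
#' @param obs_weights optional observation weights (see
#'   [grey_relational()]).
#' @param exclude traits to leave out of the factor set entirely.
#' @return data frame with columns `target`, `factor`, `correlation`,
#'   `relevance`, `rank`.
#' @export
grey_relational_table <- function(mat, targets, rho = 0.5,
                                  obs_weights = NULL, exclude = character(0)) {
  mat <- as.matrix(mat)
  norm <- min_max_normalize(mat)
  out <- list()
  for (tg in targets) {
    fac <- setdiff(colnames(mat), c(targets, exclude))
    gr <- grey_relational(norm[, tg], norm[, fac, drop = FALSE], rho = rho,
                          obs_weights = obs_weights)
    r <- vapply(fac, function(f) stats::cor(mat[, f], mat[, tg]), numeric(1))
    out[[tg]] <- data.frame(target = tg, factor = fac, correlation = r,
                            relevance = gr$gamma, rank = gr$rank,
                            row.names = NULL)
  }
  do.call(rbind, out)
}

#' PCA trait contributions
#'
#' Principal component analysis on the correlation scale.  Axes are
#' retained until the cumulative explained variance reaches `var_target`
#' (truncated at positive eigenvalues for rank-deficient input).  The
#' per-trait contribution is the eigenvalue-weighted mean of squared
#' loadings over retained axes, scaled to sum to 100; traits at or above
#' `threshold` (default the uniform share `100/m`) are flagged selected.
#'
#' @param mat germplasm x trait matrix (>= 3 rows, >= 2 columns).
#' @param var_target cumulative explained-variance target in `(0, 1]`.
#' @param threshold selection threshold on the percent contribution; `NULL`
#'   means the uniform share.
#' @return list of class `pca_contrib`: `contribution` (percent, sums to
#'   100), `selected` (logical), `n_axes`, `explained` (cumulative
#'   proportion explained by retained axes), `eigenvalues`, `loadings`.
#' @export
pca_contributions <- function(mat, var_target = 0.60, threshold = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 3 || ncol(mat) < 2) stop("need >= 3 rows and >= 2 columns")
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) stop("constant columns cannot be scaled for PCA")
  pc <- stats::prcomp(mat, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  pos <- ev > 1e-12
  ev <- ev[pos]
  prop <- ev / sum(pc$sdev^2)
  n_axes <- which(cumsum(prop) >= var_target - 1e-12)[1]
  if (is.na(n_axes)) n_axes <- length(ev)
  lam <- ev[seq_len(n_axes)]
  V2 <- pc$rotation[, seq_len(n_axes), drop = FALSE]^2
  contr <- as.vector(V2 %*% lam) / sum(lam) * 100
  names(contr) <- colnames(mat)
  thr <- if (is.null(threshold)) 100 / ncol(mat) else threshold
  structure(list(contribution = contr, selected = contr >= thr,
                 n_axes = n_axes, explained = sum(prop[seq_len(n_axes)]),
                 eigenvalues = ev, loadings = pc$rotation,
                 threshold = thr),
            class = "pca_contrib")
}

#' @export
#' @method print pca_contrib
print.pca_contrib <- function(x, ...) {
  cat(sprintf("<pca_contrib> %d axes retained, %.1f%% variance explained\n",
              x$n_axes, 100 * x$explained))
  cat(sprintf("selected (>= %.2f%%): %s\n", x$threshold,
              paste(names(x$contribution)[x$selected], collapse = ", ")))
  invisible(x)
}

#' Membership-function comprehensive scores
#'
#' Fuzzy comprehensive evaluation: each selected trait is mapped to
#' `[0, 1]` by its min-max position (reversed for cost traits) and the
#' germplasm score is the weighted mean over traits (equal weights by
#' default).  Constant traits are dropped with a warning.
#'
#' @param mat germplasm x trait matrix restricted to the selected traits.
#' @param orientations named `"benefit"`/`"cost"` vector (see
#'   [min_max_normalize()]).
#' @param weights optional per-trait aggregation weights (named or in
#'   column order); default equal.
#' @return object of class `membership_result`: `scores` (named, in
#'   `[0, 1]`), `u` (membership matrix), `traits`.
#' @export
membership_scores <- function(mat, orientations = NULL, weights = NULL) {
  mat <- as.matrix(mat)
  if (ncol(mat) == 0) stop("no selected traits")
  keep <- apply(mat, 2, function(x) diff(range(x)) > 0)
  if (!all(keep)) {
    warning("dropping constant traits: ",
            paste(colnames(mat)[!keep], collapse = ", "))
    mat <- mat[, keep, drop = FALSE]
    if (ncol(mat) == 0) stop("no non-constant selected traits")
  }
  u <- min_max_normalize(mat, orientations)
  w <- if (is.null(weights)) {
    rep(1 / ncol(u), ncol(u))
  } else {
    if (!is.null(names(weights))) weights <- weights[colnames(u)]
    weights / sum(weights)
  }
  scores <- as.vector(u %*% w)
  names(scores) <- rownames(mat)
  structure(list(scores = scores, u = u, traits = colnames(u), weights = w),
            class = "membership_result")
}

#' Hierarchical cluster cut at a fixed height
#'
#' Agglomerative clustering (Euclidean distance) cut at `cut_height`;
#' classes are labelled `A`, `B`, ... by descending class mean of the
#' clustered values (row means for multivariate input), so `A` is always
#' the best-performing class.
#'
#' @param x numeric vector or matrix (rows = items).
#' @param cut_height height at which to cut the dendrogram; a value `<= 0`
#'   makes every item its own class.
#' @param linkage one of `"average"` (default), `"single"`, `"complete"`,
#'   `"ward.D2"`.
#' @return factor of class labels, one per item.
#' @export
hcluster_cut <- function(x, cut_height,
                         linkage = c("average", "single", "complete", "ward.D2")) {
  linkage <- match.arg(linkage)
  m <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  if (nrow(m) < 2) stop("need >= 2 items")
  if (cut_height <= 0) {
    cl <- seq_len(nrow(m))
  } else {
    hc <- stats::hclust(stats::dist(m), method = linkage)
    cl <- stats::cutree(hc, h = cut_height)
  }
  means <- tapply(rowMeans(m), cl, mean)
  ord <- order(-means)
  lab <- character(length(means))
  lab[ord] <- make.unique(c(LETTERS, paste0("Z", seq_len(max(0, length(means) - 26)))))[seq_along(means)]
  out <- factor(lab[cl], levels = lab[ord])
  names(out) <- rownames(m)
  out
}
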