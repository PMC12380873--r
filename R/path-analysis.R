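#' Ridge-regression path analysis
#'
#' Decomposes each predictor trait's association with yield into a direct
#' effect (its standardized ridge coefficient) and indirect effects routed
#' through correlated predictors.  Data are standardized internally with
#' the population (1/n) standard deviation, so the ridge solution is
#' `beta(k) = (Rxx + k I)^{-1} rxy` with `Rxx` the predictor correlation
#' matrix and `rxy` the predictor-response correlations.  The indirect
#' effect of trait i via trait j is `r_ij * beta_j`; at `k = 0` with
#' full-rank predictors, direct + indirect effects reproduce the observed
#' correlations `r_iy` exactly.
#'
#' @param X germplasm x trait matrix of predictor means (>= 3 rows).
#' @param y yield vector.
#' @param k ridge parameter; a non-negative number, or `"auto"` to select
#'   by leave-one-out cross-validation over `k_grid`.
#' @param k_grid candidate grid for `k = "auto"`.
#' @return object of class `path_result`: `k`, `direct` (standardized
#'   coefficients), `indirect` (matrix, entry `[i, j]` = effect of i via
#'   j, diagonal `NA`), `total` (per-trait sums), `r_iy`, `r_squared`,
#'   `residual_path` (`sqrt(1 - R^2)`), `dropped` (constant traits).
#' @export
ridge_path <- function(X, y, k = "auto",
                       k_grid = 10^seq(-4, 0, length.out = 25)) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need >= 3 germplasms")
  stopifnot(length(y) == n)
  sd_pop <- function(v) sqrt(mean((v - mean(v))^2))
  sds <- apply(X, 2, sd_pop)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant traits: ", paste(dropped, collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  Xs <- scale(X, center = TRUE, scale = apply(X, 2, sd_pop))
  ys <- (y - mean(y)) / sd_pop(y)
  Rxx <- crossprod(Xs) / n
  rxy <- as.vector(crossprod(Xs, ys)) / n
  solve_beta <- function(Rxx, rxy, k) {
    solve(Rxx + diag(k, nrow(Rxx)), rxy)
  }
  if (identical(k, "auto")) {
    cv <- vapply(k_grid, function(kk) {
      err <- 0
      for (i in seq_len(n)) {
        Xi <- Xs[-i, , drop = FALSE]; yi <- ys[-i]
        b <- solve_beta(crossprod(Xi) / (n - 1),
                        as.vector(crossprod(Xi, yi)) / (n - 1), kk)
        err <- err + (ys[i] - sum(Xs[i, ] * b))^2
      }
      err / n
    }, numeric(1))
    k <- k_grid[which.min(cv)]
  } else {
    stopifnot(is.numeric(k), k >= 0)
  }
  beta <- solve_beta(Rxx, rxy, k)
  names(beta) <- colnames(X)
  indirect <- Rxx * matrix(beta, nrow(Rxx), length(beta), byrow = TRUE)
  diag(indirect) <- NA_real_
  dimnames(indirect) <- list(colnames(X), colnames(X))
  total <- beta + rowSums(indirect, na.rm = TRUE)
  yhat <- as.vector(Xs %*% beta)
  r2 <- 1 - mean((ys - yhat)^2)
  structure(list(k = k, direct = beta, indirect = indirect, total = total,
                 r_iy = stats::setNames(rxy, colnames(X)), r_squared = r2,
                 residual_path = sqrt(max(0, 1 - r2)), dropped = dropped),
            class = "path_result")
}

#' @export
#' @method print path_result
print.path_result <- function(x, ...) {
  cat(sprintf("<path_result> k = %.4g, R^2 = %.3f, residual path = %.3f\n",
              x$k, x$r_squared, x$residual_path))
  ord <- order(-abs(x$direct))
  print(data.frame(trait = names(x$direct)[ord],
                   direct = round(x$direct[ord], 3),
                   indirect = round((x$total - x$direct)[ord], 3),
                   total = round(x$total[ord], 3),
                   r_iy = round(x$r_iy[ord], 3), row.names = NULL))
  invisible(x)
}
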