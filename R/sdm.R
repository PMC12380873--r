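#' Clean raw occurrence records
#'
#' Drops records with non-finite coordinates, longitude/latitude outside
#' valid ranges, exact (0, 0) points, exact duplicates, and (optionally)
#' points outside a study extent.  Counts per rule are reported.
#'
#' @param points data frame with `lon`, `lat` columns.
#' @param extent optional named vector `c(xmin, xmax, ymin, ymax)`.
#' @return cleaned data frame; attribute `report` holds per-rule drop
#'   counts.
#' @export
clean_occurrences <- function(points, extent = NULL) {
  p <- points[, c("lon", "lat")]
  rep_ <- c(non_finite = 0, out_of_range = 0, zero_zero = 0,
            duplicate = 0, outside_extent = 0)
  ok <- is.finite(p$lon) & is.finite(p$lat)
  rep_["non_finite"] <- sum(!ok); p <- p[ok, ]
  ok <- p$lon >= -180 & p$lon <= 180 & p$lat >= -90 & p$lat <= 90
  rep_["out_of_range"] <- sum(!ok); p <- p[ok, ]
  ok <- !(p$lon == 0 & p$lat == 0)
  rep_["zero_zero"] <- sum(!ok); p <- p[ok, ]
  dup <- duplicated(p)
  rep_["duplicate"] <- sum(dup); p <- p[!dup, ]
  if (!is.null(extent)) {
    e <- extent
    ok <- p$lon >= e[["xmin"]] & p$lon <= e[["xmax"]] &
      p$lat >= e[["ymin"]] & p$lat <= e[["ymax"]]
    rep_["outside_extent"] <- sum(!ok); p <- p[ok, ]
  }
  if (nrow(p) == 0) stop("no occurrences left after cleaning")
  rownames(p) <- NULL
  attr(p, "report") <- rep_
  p
}

#' Spatially rarefy occurrences to one point per grid cell
#'
#' Reduces spatial autocorrelation and sampling bias by keeping at most
#' one point per cell of a regular grid (e.g. 5 arc-minutes = 1/12
#' degree); the survivor per cell is drawn uniformly at random.
#'
#' @param points data frame with `lon`, `lat`.
#' @param resolution cell size in degrees (> 0).
#' @param seed integer RNG seed.
#' @return thinned data frame, one row per occupied cell.
#' @export
rarefy_occurrences <- function(points, resolution, seed = 1) {
  if (resolution <= 0) stop("resolution must be > 0")
  cell <- paste(floor(points$lon / resolution), floor(points$lat / resolution))
  set.seed(seed)
  pick <- unlist(lapply(split(seq_len(nrow(points)), cell), function(ix) {
    if (length(ix) == 1) ix else ix[sample.int(length(ix), 1)]
  }), use.names = FALSE)
  out <- points[sort(pick), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Iterative collinearity filter on an environmental stack
#'
#' While any layer pair has `|Pearson r| >= threshold` over jointly valid
#' cells, the member of the worst pair with the larger mean absolute
#' correlation to all remaining layers is dropped.
#'
#' @param stack an [env_stack] with >= 2 layers.
#' @param threshold absolute-correlation cutoff (default 0.80: layers with
#'   `|r| < 0.80` are retained).
#' @return filtered `env_stack`; attribute `dropped` names removed layers.
#' @export
collinearity_filter <- function(stack, threshold = 0.80) {
  stopifnot(inherits(stack, "env_stack"), length(stack$layers) >= 2)
  sv <- stack_values(stack)
  keep <- colnames(sv$x)
  repeat {
    if (length(keep) < 2) break
    r <- abs(stats::cor(sv$x[, keep, drop = FALSE]))
    diag(r) <- 0
    if (max(r) < threshold) break
    worst <- which(r == max(r), arr.ind = TRUE)[1, ]
    pair <- keep[worst]
    mean_abs <- rowMeans(r[pair, , drop = FALSE])
    keep <- setdiff(keep, pair[which.max(mean_abs)])
  }
  dropped <- setdiff(names(stack$layers), keep)
  out <- env_stack(stack$layers[keep])
  attr(out, "dropped") <- dropped
  out
}

#' Sample pseudo-absence (background) points
#'
#' Uniform random cells excluding presence cells and nodata; defaults to a
#' balanced design (as many background points as presences).
#'
#' @param stack an [env_stack].
#' @param presences data frame with `lon`, `lat`.
#' @param n number of background points (default `nrow(presences)`).
#' @param seed integer RNG seed.
#' @return data frame with `lon`, `lat` at cell centers.
#' @export
pseudo_absences <- function(stack, presences, n = nrow(presences), seed = 1) {
  if (n < 1) stop("n must be >= 1")
  sv <- stack_values(stack)
  r <- stack$layers[[1]]
  pc <- raster_cell_of(r, presences$lon, presences$lat)
  pres_key <- unique(paste(pc[, 1], pc[, 2]))
  all_key <- paste(sv$cell[, 1], sv$cell[, 2])
  eligible <- which(!(all_key %in% pres_key))
  if (length(eligible) < n) {
    stop(sprintf("only %d eligible background cells for n = %d",
                 length(eligible), n))
  }
  set.seed(seed)
  idx <- eligible[sample.int(length(eligible), n)]
  data.frame(lon = sv$coords$lon[idx], lat = sv$coords$lat[idx])
}

#' AUC by the rank (Mann-Whitney) formula
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels (both classes present).
#' @return area under the ROC curve.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold-based evaluation of binary predictions
#'
#' AUC via the rank formula; the binarization threshold maximizes the true
#' skill statistic TSS = sensitivity + specificity - 1 (candidates are the
#' unique scores); Cohen's Kappa comes from the resulting confusion table.
#'
#' @param scores numeric prediction scores in any monotone scale.
#' @param labels 0/1 labels (both classes present).
#' @return list with `auc`, `tss`, `kappa`, `sensitivity`, `specificity`,
#'   `threshold`.
#' @export
evaluate_binary <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  auc <- auc_rank(scores, labels)
  cand <- sort(unique(scores))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  best <- list(tss = -Inf)
  for (th in cand) {
    pred <- scores >= th
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    sens <- tp / n1; spec <- (n0 - fp) / n0
    tss <- sens + spec - 1
    if (tss > best$tss) {
      best <- list(tss = tss, sens = sens, spec = spec, threshold = th,
                   tp = tp, fp = fp)
    }
  }
  tp <- best$tp; fp <- best$fp; fn <- n1 - tp; tn <- n0 - fp
  n <- n1 + n0
  po <- (tp + tn) / n
  pe <- ((tp + fp) * n1 + (fn + tn) * n0) / n^2
  kappa <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  list(auc = auc, tss = best$tss, kappa = kappa,
       sensitivity = best$sens, specificity = best$spec,
       threshold = best$threshold)
}

# ---- learner families ------------------------------------------------------
# Each learner is fit(X, y) -> model with a matching prediction routine
# returning probabilities in [0, 1].  X is a numeric matrix of covariates.

poly_expand <- function(X) cbind(X, X^2, deparse.level = 0)

fit_one_learner <- function(name, X, y) {
  switch(name,
    glm = list(kind = "glmnet",
               fit = glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                                    lambda = 0.01)),
    poly = list(kind = "glmnet_poly",
                fit = glmnet::glmnet(poly_expand(X), y, family = "binomial",
                                     alpha = 0, lambda = 0.01)),
    gam = {
      df <- as.data.frame(X); df$.y <- y
      terms <- paste(sprintf("s(%s, k = 5)", colnames(X)), collapse = " + ")
      list(kind = "gam",
           fit = mgcv::gam(stats::as.formula(paste(".y ~", terms)),
                           family = stats::binomial(), data = df,
                           method = "REML"))
    },
    knn = {
      mu <- colMeans(X); sdv <- apply(X, 2, stats::sd); sdv[sdv == 0] <- 1
      list(kind = "knn", X = sweep(sweep(X, 2, mu), 2, sdv, "/"),
           y = y, mu = mu, sd = sdv, k = min(15L, nrow(X) - 1L))
    },
    stump = list(kind = "stump", fit = fit_boosted_stumps(X, y, n_rounds = 40)),
    stop("unknown learner: ", name)
  )
}

predict_one_learner <- function(model, X) {
  switch(model$kind,
    glmnet = as.vector(stats::predict(model$fit, X, type = "response")),
    glmnet_poly = as.vector(stats::predict(model$fit, poly_expand(X),
                                           type = "response")),
    gam = as.vector(stats::predict(model$fit, as.data.frame(X),
                                   type = "response")),
    knn = knn_prob(model, X),
    stump = predict_boosted_stumps(model$fit, X),
    stop("unknown model kind")
  )
}

knn_prob <- function(model, X) {
  Xs <- sweep(sweep(X, 2, model$mu), 2, model$sd, "/")
  tr <- model$X; y <- model$y; k <- model$k
  tr_sq <- rowSums(tr^2)
  out <- numeric(nrow(Xs))
  chunk <- 500L
  for (s in seq(1L, nrow(Xs), by = chunk)) {
    ix <- s:min(s + chunk - 1L, nrow(Xs))
    d2 <- outer(rowSums(Xs[ix, , drop = FALSE]^2), tr_sq, "+") -
      2 * Xs[ix, , drop = FALSE] %*% t(tr)
    out[ix] <- apply(d2, 1, function(d) mean(y[order(d)[seq_len(k)]]))
  }
  out
}

# AdaBoost with depth-1 decision stumps; thresholds searched over deciles
fit_boosted_stumps <- function(X, y, n_rounds = 40) {
  n <- nrow(X); m <- ncol(X)
  yy <- ifelse(y == 1, 1, -1)
  w <- rep(1 / n, n)
  cand <- lapply(seq_len(m), function(j)
    unique(stats::quantile(X[, j], probs = seq(0.05, 0.95, by = 0.05),
                           names = FALSE)))
  stumps <- vector("list", n_rounds)
  for (t in seq_len(n_rounds)) {
    best <- list(err = Inf)
    for (j in seq_len(m)) {
      xj <- X[, j]
      for (th in cand[[j]]) {
        pred <- ifelse(xj >= th, 1, -1)
        err <- sum(w[pred != yy])
        if (err < best$err) best <- list(err = err, j = j, th = th, pol = 1)
        if (1 - err < best$err) best <- list(err = 1 - err, j = j, th = th, pol = -1)
      }
    }
    err <- max(best$err, 1e-10)
    if (err >= 0.5) break
    alpha <- 0.5 * log((1 - err) / err)
    pred <- ifelse(X[, best$j] >= best$th, 1, -1) * best$pol
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
    stumps[[t]] <- list(j = best$j, th = best$th, pol = best$pol,
                        alpha = alpha)
  }
  list(stumps = Filter(Negate(is.null), stumps))
}

predict_boosted_stumps <- function(model, X) {
  f <- numeric(nrow(X))
  for (s in model$stumps) {
    f <- f + s$alpha * ifelse(X[, s$j] >= s$th, 1, -1) * s$pol
  }
  stats::plogis(2 * f)
}

#' Available SDM learner families
#'
#' @return character vector of learner names accepted by
#'   [fit_ensemble()]: ridge-regularized linear logistic (`glm`),
#'   degree-2 polynomial logistic (`poly`), spline logistic (`gam`),
#'   k-nearest-neighbour probability (`knn`) and boosted decision stumps
#'   (`stump`).
#' @export
sdm_learners <- function() c("glm", "poly", "gam", "knn", "stump")

#' Fit an AUC-weighted ensemble species distribution model
#'
#' For each of `repeats` stratified holdout splits (`train_fraction` of
#' each class for training), every learner family is fitted on the
#' training part and scored by AUC on the holdout.  Learners whose mean
#' holdout AUC reaches `auc_threshold` enter the consensus with weights
#' proportional to their AUC; the consensus suitability raster is the
#' weighted mean of the per-learner probability rasters refitted on all
#' data.  Ensemble AUC / Kappa / TSS are computed on the pooled holdout
#' predictions at the TSS-maximizing threshold.
#'
#' @param presences,background data frames with `lon`, `lat`.
#' @param stack an [env_stack] of (collinearity-filtered) covariates.
#' @param learners subset of [sdm_learners()]; >= 3 families recommended.
#' @param repeats number of holdout repetitions.
#' @param train_fraction fraction of each class used for training.
#' @param auc_threshold inclusion threshold on mean holdout AUC.
#' @param seed integer RNG seed (controls splits only).
#' @return object of class `ensemble_model`: `learner_auc`, `included`,
#'   `weights`, `consensus` (an [env_raster]), `metrics` (list from
#'   [evaluate_binary()] on pooled holdouts), `learner_correlation`,
#'   `predictions` (valid-cell matrix, one column per included learner),
#'   `models`, `data`.
#' @export
fit_ensemble <- function(presences, background, stack,
                         learners = sdm_learners(), repeats = 10,
                         train_fraction = 0.75, auc_threshold = 0.75,
                         seed = 1) {
  stopifnot(length(learners) >= 1, all(learners %in% sdm_learners()))
  Xp <- extract_env(stack, presences)
  Xb <- extract_env(stack, background)
  ok_p <- stats::complete.cases(Xp); ok_b <- stats::complete.cases(Xb)
  X <- rbind(Xp[ok_p, , drop = FALSE], Xb[ok_b, , drop = FALSE])
  y <- c(rep(1L, sum(ok_p)), rep(0L, sum(ok_b)))
  n <- length(y)
  set.seed(seed)
  auc_mat <- matrix(NA_real_, repeats, length(learners),
                    dimnames = list(NULL, learners))
  pooled <- stats::setNames(vector("list", length(learners)), learners)
  pooled_y <- list()
  for (rep_i in seq_len(repeats)) {
    tr <- unlist(lapply(split(seq_len(n), y), function(ix) {
      ix[sample.int(length(ix), max(1L, round(train_fraction * length(ix))))]
    }), use.names = FALSE)
    ho <- setdiff(seq_len(n), tr)
    pooled_y[[rep_i]] <- y[ho]
    for (lr in learners) {
      mod <- fit_one_learner(lr, X[tr, , drop = FALSE], y[tr])
      pr <- predict_one_learner(mod, X[ho, , drop = FALSE])
      auc_mat[rep_i, lr] <- auc_rank(pr, y[ho])
      pooled[[lr]][[rep_i]] <- pr
    }
  }
  learner_auc <- colMeans(auc_mat)
  included <- learner_auc >= auc_threshold
  if (!any(included)) {
    stop(sprintf(paste("no learner reached the AUC threshold %.2f",
                       "(best: %s = %.3f); inspect the covariates or",
                       "lower the threshold"),
                 auc_threshold, names(which.max(learner_auc)),
                 max(learner_auc)))
  }
  w <- learner_auc[included] / sum(learner_auc[included])
  # refit on all data, predict the raster
  sv <- stack_values(stack)
  models <- lapply(learners[included], function(lr) fit_one_learner(lr, X, y))
  names(models) <- learners[included]
  preds <- vapply(models, function(m) predict_one_learner(m, sv$x),
                  numeric(nrow(sv$x)))
  if (!is.matrix(preds)) preds <- matrix(preds, ncol = length(models),
                                         dimnames = list(NULL, names(models)))
  consensus_vals <- as.vector(preds %*% w)
  r0 <- stack$layers[[1]]
  cm <- matrix(NA_real_, nrow(r0$values), ncol(r0$values))
  cm[sv$cell] <- consensus_vals
  consensus <- env_raster(cm, r0$xllcorner, r0$yllcorner, r0$cellsize)
  # pooled-holdout ensemble metrics
  hy <- unlist(pooled_y)
  ens_scores <- Reduce(`+`, Map(function(lr, wt) wt * unlist(pooled[[lr]]),
                                names(w), w))
  metrics <- evaluate_binary(ens_scores, hy)
  corr <- if (ncol(preds) > 1) stats::cor(preds) else
    matrix(1, 1, 1, dimnames = list(names(models), names(models)))
  structure(list(learner_auc = learner_auc, included = included,
                 weights = w, consensus = consensus, metrics = metrics,
                 learner_correlation = corr, predictions = preds,
                 models = models, stack_names = names(stack$layers),
                 data = list(X = X, y = y), cells = sv$cell),
            class = "ensemble_model")
}

#' @export
#' @method print ensemble_model
print.ensemble_model <- function(x, ...) {
  cat("<ensemble_model>\n  mean holdout AUC per learner:\n")
  print(round(x$learner_auc, 3))
  cat(sprintf("  included: %s\n",
              paste(names(x$weights), collapse = ", ")))
  cat(sprintf("  ensemble AUC %.3f, Kappa %.3f, TSS %.3f\n",
              x$metrics$auc, x$metrics$kappa, x$metrics$tss))
  invisible(x)
}

#' Permutation variable importance of the ensemble
#'
#' For each covariate, its cell values are permuted (seeded) and the
#' consensus re-predicted; importance is `1 - Pearson r` between intact
#' and permuted predictions, floored at 0 and normalized to sum to 100.
#'
#' @param model an `ensemble_model` from [fit_ensemble()].
#' @param stack the [env_stack] the model was fitted on.
#' @param seed integer RNG seed.
#' @return named numeric vector of percent importances summing to 100.
#' @export
variable_importance <- function(model, stack, seed = 1) {
  sv <- stack_values(stack)
  base <- as.vector(model$predictions %*% model$weights)
  set.seed(seed)
  raw <- vapply(colnames(sv$x), function(v) {
    xp <- sv$x
    xp[, v] <- xp[sample.int(nrow(xp)), v]
    pr <- vapply(model$models, function(m) predict_one_learner(m, xp),
                 numeric(nrow(xp)))
    if (!is.matrix(pr)) pr <- matrix(pr, ncol = length(model$models))
    pred <- as.vector(pr %*% model$weights)
    1 - stats::cor(base, pred)
  }, numeric(1))
  raw[raw < 0] <- 0
  if (sum(raw) == 0) raw[] <- 1
  100 * raw / sum(raw)
}
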