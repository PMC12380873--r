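# Shared fixture builders; everything is generated in code, no stored data.

# small raster with deterministic values
tiny_raster <- function(nr = 4, nc = 5, xll = 100, yll = 30, cs = 1,
                        vals = NULL) {
  if (is.null(vals)) vals <- matrix(seq_len(nr * nc) / (nr * nc), nr, nc)
  env_raster(vals, xll, yll, cs)
}

# stack of `n` layers with seeded random values on one grid
tiny_stack <- function(n = 3, nr = 6, nc = 6, seed = 1, xll = 0, yll = 0,
                       cs = 1) {
  set.seed(seed)
  layers <- lapply(seq_len(n), function(i) {
    env_raster(matrix(stats::rnorm(nr * nc), nr, nc), xll, yll, cs)
  })
  names(layers) <- sprintf("bio%02d", seq_len(n))
  env_stack(layers)
}

# independent oracle: entropy weights written as a direct formula transcription
oracle_entropy_weights <- function(X) {
  n <- nrow(X); m <- ncol(X)
  e <- numeric(m)
  for (j in seq_len(m)) {
    s <- sum(X[, j])
    if (s == 0) { e[j] <- 1; next }
    acc <- 0
    for (i in seq_len(n)) {
      p <- X[i, j] / s
      if (p > 0) acc <- acc + p * log(p)
    }
    e[j] <- -acc / log(n)
  }
  d <- 1 - e
  d[abs(d) < 1e-15] <- 0
  if (sum(d) == 0) rep(1 / m, m) else d / sum(d)
}

# independent oracle: Deng grey relational degree, step by step
oracle_grey <- function(ref, F, rho, w = NULL) {
  n <- nrow(F); m <- ncol(F)
  if (is.null(w)) w <- rep(1 / n, n)
  D <- abs(F - ref)
  dmin <- min(D); dmax <- max(D)
  g <- numeric(m)
  for (i in seq_len(m)) {
    xi <- (dmin + rho * dmax) / (D[, i] + rho * dmax)
    g[i] <- sum(w * xi)
  }
  g
}

# independent oracle: AUC by brute-force pair counting
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# independent oracle: optimal k-partition of sorted values by exhaustive search
oracle_jenks_ss <- function(v, k) {
  v <- sort(v)
  n <- length(v)
  ss <- function(x) sum((x - mean(x))^2)
  best <- Inf
  cuts <- utils::combn(n - 1, k - 1)
  if (k == 1) return(ss(v))
  for (c in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, c], n)
    tot <- 0
    for (i in seq_len(k)) tot <- tot + ss(v[(b[i] + 1):b[i + 1]])
    best <- min(best, tot)
  }
  best
}

jenks_ss_of_breaks <- function(v, breaks) {
  cls <- findInterval(v, breaks, left.open = TRUE) + 1
  sum(tapply(v, cls, function(x) sum((x - mean(x))^2)))
}

# small fertile trait world for scoring tests
small_trait_world <- function(seed = 1, n_germplasm = 20, ...) {
  cfg <- trait_sim_config(n_germplasm = n_germplasm, seed = seed,
                          fertility_fail_fraction = 0.25, ...)
  sim <- generate_trait_table(cfg)
  tab <- suppressMessages(filter_fertility(sim$table))
  list(sim = sim, table = tab, means = trait_means(tab),
       orientations = stats::setNames(sim$traits$orientation,
                                      sim$traits$trait))
}
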