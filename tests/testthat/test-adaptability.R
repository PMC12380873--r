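# small shared world: 6x6 grid, 2x2 regions, 3 env layers
adapt_world <- function(seed = 60) {
  set.seed(seed)
  st <- tiny_stack(3, nr = 6, nc = 6, seed = seed, xll = 0, yll = 0, cs = 1)
  suit <- env_raster(matrix(stats::runif(36), 6, 6), 0, 0, 1)
  regs <- generate_regions(c(xmin = 0, xmax = 6, ymin = 0, ymax = 6), 2, 2)
  cm <- classify_suitability(suit, jenks_breaks(as.vector(suit$values), 3))
  list(stack = st, suit = suit, regions = regs, classmap = cm)
}

test_that("region profiles are exact zonal means", {
  w <- adapt_world()
  prof <- region_profiles(w$suit, w$stack, w$regions, classmap = w$classmap)
  expect_equal(nrow(prof), 4)
  # hand-computed mean over region SP01 (x 0-3, y 0-3 = rows 4-6, cols 1-3)
  sub <- w$suit$values[4:6, 1:3]
  expect_equal(prof$suit_mean[prof$region_id == "SP01"], mean(sub))
  e1 <- w$stack$layers[[1]]$values[4:6, 1:3]
  expect_equal(prof$env_bio01[prof$region_id == "SP01"], mean(e1))

  # constant suitability: every region mean equals it
  flat <- env_raster(matrix(0.6, 6, 6), 0, 0, 1)
  pf <- region_profiles(flat, w$stack, w$regions)
  expect_true(all(pf$suit_mean == 0.6))

  # a one-cell region reports that cell's values
  tiny <- region_set("T", list(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))))
  pt <- region_profiles(w$suit, w$stack, tiny)
  expect_equal(pt$n_cells, 1)
  expect_equal(pt$suit_mean, w$suit$values[6, 1])

  expect_error(region_profiles(w$suit, w$stack, region_set(character(0), list())),
               "empty")
})

test_that("dissimilarity screening picks the best-aligned index", {
  w <- adapt_world(61)
  prof <- region_profiles(w$suit, w$stack, w$regions)

  # single candidate: returned unconditionally
  one <- optimal_dissimilarity(prof, candidates = "manhattan")
  expect_equal(one$chosen, "manhattan")

  # profiles equal to suitability itself: every index is perfectly
  # rank-aligned, first candidate wins by the tie rule
  p1 <- prof
  p1[grep("^env_", names(p1))] <- NULL
  p1$env_only <- prof$suit_mean
  tie <- optimal_dissimilarity(p1, candidates = c("euclidean", "manhattan"))
  expect_equal(tie$chosen, "euclidean")
  expect_equal(unname(tie$rank_correlation), c(1, 1))

  # scale-imbalanced features: gower (range-normalized) beats raw euclidean
  set.seed(62)
  n <- 8
  signal <- stats::runif(n)
  p2 <- data.frame(region_id = sprintf("SP%02d", 1:n), n_cells = 1,
                   suit_mean = signal, suit_median = signal,
                   suitable_area_km2 = NA_real_,
                   env_signal = signal,
                   env_noise = stats::rnorm(n, 0, 1000))
  sc <- optimal_dissimilarity(p2, candidates = c("euclidean", "gower"))
  expect_gte(sc$rank_correlation[["gower"]], sc$rank_correlation[["euclidean"]])
})

test_that("Mantel statistics and p-values behave", {
  set.seed(63)
  x <- matrix(stats::rnorm(12), 6, 2)
  D <- as.matrix(stats::dist(x))
  self <- mantel_test(D, D, permutations = 99, seed = 1)
  expect_equal(self$statistic, 1)
  expect_true(self$exact)  # n = 6 enumerates 720 permutations
  expect_lte(self$p_value, 24 / 720 + 1e-12)

  expect_error(mantel_test(D, D[1:5, 1:5]), "matching|symmetric")
  D2 <- D; D2[1, 2] <- 99
  expect_error(mantel_test(D, D2), "symmetric")
})

test_that("sampled Mantel p converges to the exact enumeration for n = 4, 5", {
  for (n in 4:5) {
    set.seed(64 + n)
    d1 <- as.matrix(stats::dist(stats::rnorm(n)))
    d2 <- as.matrix(stats::dist(stats::rnorm(n)))
    ex <- mantel_test(d1, d2, exact = TRUE)
    ps <- vapply(1:10, function(s) {
      mantel_test(d1, d2, permutations = 999, seed = s, exact = FALSE)$p_value
    }, numeric(1))
    mc_se <- sqrt(ex$p_value * (1 - ex$p_value) / 999)
    expect_lt(abs(mean(ps) - ex$p_value), 3 * mc_se + 2 / 999)
  }
})

test_that("region similarity matrix reproduces Spearman structure", {
  w <- adapt_world(65)
  prof <- region_profiles(w$suit, w$stack, w$regions)
  rs <- region_similarity_matrix(prof)
  expect_equal(unname(diag(rs)), rep(1, nrow(prof)))
  expect_true(all(rs >= -1 & rs <= 1))
  fx <- as.matrix(prof[, grep("^env_", names(prof))])
  expect_equal(rs[1, 2],
               stats::cor(fx[1, ], fx[2, ], method = "spearman"))
})

test_that("adaptability scores gate on suitability and similarity", {
  w <- adapt_world(66)
  prof <- region_profiles(w$suit, w$stack, w$regions, classmap = w$classmap)
  # maximal case: force one region to match the trial profile exactly,
  # with suitability 1 and a germplasm of membership 1
  trial <- stats::setNames(as.numeric(prof[1, grep("^env_", names(prof))]),
                           grep("^env_", names(prof), value = TRUE))
  prof$suit_mean[1] <- 1
  mem <- structure(list(scores = c(G1 = 1, G2 = 0.4), u = NULL,
                        traits = NULL, weights = NULL),
                   class = "membership_result")
  am <- adaptability_matrix(mem, prof, trial, permutations = 49, seed = 1)
  expect_equal(am$scores["G1", prof$region_id[1]], 1)
  expect_true(all(am$scores >= 0 & am$scores <= 1))

  # zero suitability gates everything to zero
  prof0 <- prof; prof0$suit_mean <- 0
  am0 <- suppressWarnings(adaptability_matrix(mem, prof0, trial,
                                              permutations = 49, seed = 1))
  expect_true(all(am0$scores == 0))

  # monotonicity in the membership score with everything else fixed
  expect_true(all(am$scores["G1", ] >= am$scores["G2", ]))
})

test_that("the engineered most-similar region wins for the top germplasm", {
  set.seed(67)
  n_reg <- 6
  feats <- matrix(stats::rnorm(n_reg * 4), n_reg, 4)
  trial <- c(env_a = 1, env_b = 2, env_c = 3, env_d = 4)
  feats[3, ] <- c(1.1, 2.1, 3.1, 4.1)  # region 3 mirrors the trial site ranks
  prof <- data.frame(region_id = sprintf("SP%02d", 1:n_reg), n_cells = 1,
                     suit_mean = 0.8, suit_median = 0.8,
                     suitable_area_km2 = 100,
                     env_a = feats[, 1], env_b = feats[, 2],
                     env_c = feats[, 3], env_d = feats[, 4])
  mem <- structure(list(scores = c(BEST = 0.9, OK = 0.5)),
                   class = "membership_result")
  am <- adaptability_matrix(mem, prof, trial, permutations = 49, seed = 2)
  expect_equal(names(which.max(am$scores["BEST", ])), "SP03")
})

test_that("relabelling regions permutes the matrix equivariantly", {
  w <- adapt_world(68)
  prof <- region_profiles(w$suit, w$stack, w$regions, classmap = w$classmap)
  trial <- stats::setNames(as.numeric(prof[2, grep("^env_", names(prof))]),
                           grep("^env_", names(prof), value = TRUE))
  mem <- structure(list(scores = c(G1 = 0.9, G2 = 0.3)),
                   class = "membership_result")
  am1 <- adaptability_matrix(mem, prof, trial, permutations = 49, seed = 3)
  perm <- c(3, 1, 4, 2)
  am2 <- adaptability_matrix(mem, prof[perm, ], trial, permutations = 49,
                             seed = 3)
  expect_equal(am2$scores[, prof$region_id], am1$scores)
})
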