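test_that("occurrence cleaning applies each rule and reports counts", {
  raw <- data.frame(
    lon = c(0, 10, 10, 10, 200, NA, 50),
    lat = c(0, 20, 20, 20, 10, 5, 80)
  )
  out <- clean_occurrences(raw)
  rep_ <- attr(out, "report")
  expect_equal(nrow(out), 2)  # (10,20) once and (50,80) survive
  expect_equal(unname(rep_["zero_zero"]), 1)
  expect_equal(unname(rep_["duplicate"]), 2)
  expect_equal(unname(rep_["out_of_range"]), 1)
  expect_equal(unname(rep_["non_finite"]), 1)

  ext <- c(xmin = 0, xmax = 20, ymin = 0, ymax = 30)
  pts <- data.frame(lon = c(5, 15, 25, 30, -5, 10, 12, 13, 14, 1),
                    lat = c(5, 15, 25, 10, 5, 10, 12, 13, 14, 1))
  out2 <- clean_occurrences(pts, ext)
  expect_equal(nrow(out2), 7)

  expect_error(clean_occurrences(data.frame(lon = 0, lat = 0)), "no occurrences")
})

test_that("rarefaction keeps one point per cell", {
  one <- data.frame(lon = c(0.1, 0.2, 0.3), lat = c(0.1, 0.15, 0.05))
  expect_equal(nrow(rarefy_occurrences(one, 1, seed = 1)), 1)

  spread <- data.frame(lon = c(0.5, 1.5, 2.5), lat = c(0.5, 0.5, 0.5))
  expect_equal(rarefy_occurrences(spread, 1, seed = 1), spread)

  set.seed(40)
  pts <- data.frame(lon = stats::runif(100, 0, 5), lat = stats::runif(100, 0, 5))
  rar <- rarefy_occurrences(pts, 1, seed = 2)
  occupied <- length(unique(paste(floor(pts$lon), floor(pts$lat))))
  expect_equal(nrow(rar), occupied)
  expect_identical(rarefy_occurrences(pts, 1, seed = 2), rar)
})

test_that("collinearity filter drops redundant layers", {
  st <- tiny_stack(3, seed = 41)
  dup <- env_stack(c(st$layers, list(bio03copy = st$layers[[3]])))
  out <- collinearity_filter(dup, 0.8)
  expect_length(attr(out, "dropped"), 1)
  expect_true(attr(out, "dropped") %in% c("bio03", "bio03copy"))

  # independent noise layers at this size stay below |r| = 0.8
  big <- tiny_stack(4, nr = 20, nc = 20, seed = 42)
  kept <- collinearity_filter(big, 0.8)
  expect_length(attr(kept, "dropped"), 0)
  expect_length(kept$layers, 4)
})

test_that("pseudo-absences avoid presence cells and are reproducible", {
  st <- tiny_stack(2, nr = 10, nc = 10, seed = 43)
  pres <- data.frame(lon = c(0.5, 1.5, 2.5), lat = c(0.5, 0.5, 1.5))
  bg <- pseudo_absences(st, pres, seed = 1)
  expect_equal(nrow(bg), nrow(pres))  # balanced by default
  pk <- paste(floor(pres$lon), floor(pres$lat))
  bk <- paste(floor(bg$lon), floor(bg$lat))
  expect_length(intersect(pk, bk), 0)
  expect_identical(pseudo_absences(st, pres, seed = 1), bg)
  expect_error(pseudo_absences(st, pres, n = 1e5, seed = 1), "eligible")
})

test_that("rank AUC equals brute-force pair counting", {
  set.seed(44)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- round(stats::runif(n), 2)  # ties on purpose
    expect_equal(auc_rank(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("binary evaluation metrics hit their closed forms", {
  perfect <- evaluate_binary(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$tss, 1)
  expect_equal(perfect$kappa, 1)

  # constructed confusion table TP=8 FN=2 TN=7 FP=3 at the max-TSS threshold
  scores <- c(rep(0.9, 8), rep(0.1, 2), rep(0.9, 3), rep(0.1, 7))
  labels <- c(rep(1, 10), rep(0, 10))
  ev <- evaluate_binary(scores, labels)
  expect_equal(ev$tss, 0.8 + 0.7 - 1)
  expect_equal(ev$sensitivity, 0.8)
  expect_equal(ev$specificity, 0.7)

  rev <- evaluate_binary(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))
  expect_equal(rev$auc, 0)
  expect_error(evaluate_binary(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("the ensemble separates separable data and not shuffled labels", {
  st <- tiny_stack(3, nr = 15, nc = 15, seed = 45)
  sv <- stack_values(st)
  sep <- sv$x[, 1] > stats::median(sv$x[, 1])
  pres <- sv$coords[sep, ]
  bg <- sv$coords[!sep, ]
  em <- fit_ensemble(pres, bg, st, learners = c("glm", "knn", "stump"),
                     repeats = 2, seed = 1)
  expect_gt(max(em$learner_auc), 0.99)
  expect_gt(em$metrics$auc, 0.99)
  # consensus is a convex combination of included learner predictions
  expect_true(all(em$consensus$values >= 0 & em$consensus$values <= 1,
                  na.rm = TRUE))
  lo <- apply(em$predictions, 1, min); hi <- apply(em$predictions, 1, max)
  cons <- as.vector(em$consensus$values)[!is.na(as.vector(em$consensus$values))]
  expect_true(all(cons >= lo - 1e-12 & cons <= hi + 1e-12))
  expect_equal(sum(em$weights), 1)

  # shuffled labels: near-chance AUC, nothing passes 0.75
  set.seed(46)
  shuffle <- sample(nrow(sv$coords))
  pres_r <- sv$coords[shuffle[1:80], ]
  bg_r <- sv$coords[shuffle[81:160], ]
  expect_error(
    fit_ensemble(pres_r, bg_r, st, learners = c("glm", "poly"),
                 repeats = 3, seed = 2),
    "threshold")
})

test_that("ensembles are reproducible under a fixed seed", {
  L <- generate_landscape(landscape_sim_config(
    extent = c(xmin = 0, xmax = 10, ymin = 0, ymax = 10), resolution = 0.5,
    n_layers = 3, seed = 47))
  occ <- generate_occurrences(L$truth, 80, seed = 5)
  bg <- pseudo_absences(L$stack, occ, seed = 6)
  a <- fit_ensemble(occ, bg, L$stack, learners = c("glm", "stump"),
                    repeats = 2, auc_threshold = 0.5, seed = 7)
  b <- fit_ensemble(occ, bg, L$stack, learners = c("glm", "stump"),
                    repeats = 2, auc_threshold = 0.5, seed = 7)
  expect_identical(a$consensus$values, b$consensus$values)
  expect_identical(a$learner_auc, b$learner_auc)
})

test_that("variable importance sums to 100 and ignores unused layers", {
  L <- generate_landscape(landscape_sim_config(
    extent = c(xmin = 0, xmax = 12, ymin = 0, ymax = 12), resolution = 0.4,
    n_layers = 4, true_coefficients = c(3, -2), seed = 48))
  occ <- generate_occurrences(L$truth, 200, seed = 8)
  bg <- pseudo_absences(L$stack, occ, seed = 9)
  em <- fit_ensemble(occ, bg, L$stack, learners = c("glm", "poly"),
                     repeats = 3, auc_threshold = 0.5, seed = 10)
  imp <- variable_importance(em, L$stack, seed = 11)
  expect_equal(sum(imp), 100, tolerance = 1e-9)
  # the two coefficient-bearing layers dominate
  expect_true(all(c("bio01", "bio02") %in%
                    names(sort(imp, decreasing = TRUE))[1:2]))
  expect_lt(imp[["bio04"]], 10)
})
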