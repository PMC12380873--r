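#' Default demonstration pipeline configuration
#'
#' Methodological defaults follow the field workflow this package
#' implements: 62 germplasms with 19/62 fertility failure and 10
#' replicates, grey resolution coefficient 0.5, 75/25 holdout with AUC
#' inclusion threshold 0.75, three-level natural-breaks classification.
#' Simulation sizes (40 x 40 landscape, 300 presences, 3 holdout repeats,
#' 199 permutations) are chosen so a full run completes within a few
#' minutes on one CPU; every stage seed is derived from the master seed.
#'
#' @param seed master integer seed.
#' @param outdir output directory for artifacts.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1, outdir = "forageadapt-demo") {
  list(
    seed = seed, outdir = outdir,
    stages = list(simulate = TRUE, traits = TRUE, score = TRUE, path = TRUE,
                  sdm = TRUE, geo = TRUE, adapt = TRUE),
    traits = list(n_germplasm = 62, n_traits = 23, n_reps = 10,
                  germplasm_sd = 5, replicate_sd = 1,
                  fertility_fail_fraction = 19 / 62),
    grey = list(rho = 0.5, targets = c("HY", "FY")),
    pca = list(var_target = 0.60),
    cluster = list(cut_heights = list(hy = 40, fy = 100, membership = 0.2),
                   linkage = "average"),
    ridge = list(k = "auto"),
    landscape = list(extent = c(xmin = 88, xmax = 105, ymin = 26, ymax = 39),
                     resolution = 17 / 40, n_layers = 6, smoothness = 2,
                     n_presence = 300,
                     true_coefficients = c(2.5, -1.8), intercept = -0.5),
    sdm = list(learners = c("glm", "poly", "gam", "knn", "stump"),
               repeats = 3, train_fraction = 0.75, auc_threshold = 0.75,
               rarefy_resolution = 1 / 12, collinearity_threshold = 0.80),
    geo = list(breaks_k = 3),
    regions = list(n_rows = 3, n_cols = 3),
    adapt = list(permutations = 199,
                 trial_site = c(lon = 102.53, lat = 32.78))
  )
}

write_csv_ <- function(x, path) utils::write.csv(x, path, row.names = FALSE)

#' Run the full synthetic-to-adaptability pipeline
#'
#' Executes simulate, traits, score, path, sdm, geo and adapt stages in
#' order, writing plain-text artifacts (CSV/JSON/ASC/GeoJSON) into
#' `cfg$outdir`.  Later stages read the in-memory results of earlier
#' ones; a disabled upstream stage makes dependent stages fail with a
#' message naming the missing stage.  Fully seeded: two runs with the
#' same configuration produce byte-identical artifacts.
#'
#' @param cfg configuration list (see [default_pipeline_config()]).
#' @return invisibly, a list with the in-memory stage results and
#'   `outdir`.
#' @export
run_pipeline <- function(cfg = default_pipeline_config()) {
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list(outdir = outdir)
  on <- function(st) isTRUE(cfg$stages[[st]])
  need <- function(st, dep, producer) {
    if (is.null(res[[dep]])) {
      stop(sprintf("stage '%s' requires stage '%s' to have run (missing '%s')",
                   st, producer, dep))
    }
  }
  seed_for <- function(offset) (cfg$seed * 1000L + offset) %% .Machine$integer.max

  if (on("simulate")) {
    message("[simulate] trait table, landscape, occurrences, regions")
    tcfg <- do.call(trait_sim_config,
                    c(cfg$traits, list(seed = seed_for(1))))
    res$sim_traits <- generate_trait_table(tcfg)
    write_trait_csv(res$sim_traits$table, file.path(outdir, "traits.csv"))
    lcfg <- do.call(landscape_sim_config,
                    c(cfg$landscape, list(seed = seed_for(2))))
    res$landscape <- generate_landscape(lcfg)
    for (nm in names(res$landscape$stack$layers)) {
      write_ascii_grid(res$landscape$stack$layers[[nm]],
                       file.path(outdir, paste0("env_", nm, ".asc")))
    }
    write_ascii_grid(res$landscape$truth, file.path(outdir, "truth.asc"))
    res$occurrences <- generate_occurrences(res$landscape$truth,
                                            lcfg$n_presence,
                                            seed = seed_for(3))
    write_csv_(res$occurrences, file.path(outdir, "occurrences.csv"))
    res$regions <- generate_regions(lcfg$extent, cfg$regions$n_rows,
                                    cfg$regions$n_cols)
    write_regions_geojson(res$regions, file.path(outdir, "regions.geojson"))
  }

  if (on("traits")) {
    need("traits", "sim_traits", "simulate")
    message("[traits] descriptive statistics and correlations")
    tab <- suppressMessages(filter_fertility(res$sim_traits$table))
    res$trait_table <- tab
    res$trait_means <- trait_means(tab)
    write_csv_(describe_traits(tab), file.path(outdir, "table1.csv"))
    pm <- pearson_matrix(res$trait_means)
    write_csv_(data.frame(trait = rownames(pm$r), round(pm$r, 4)),
               file.path(outdir, "correlations.csv"))
    sh <- shannon_by_germplasm(tab)
    write_csv_(data.frame(germplasm_id = names(sh), shannon = sh),
               file.path(outdir, "shannon.csv"))
  }

  if (on("score")) {
    need("score", "trait_means", "traits")
    message("[score] entropy weights, grey relations, PCA, membership")
    ori <- stats::setNames(res$sim_traits$traits$orientation,
                           res$sim_traits$traits$trait)
    norm <- min_max_normalize(res$trait_means, ori)
    res$weights <- entropy_weights(norm)
    write_csv_(data.frame(trait = names(res$weights$weights),
                          weight = res$weights$weights,
                          entropy = res$weights$entropy),
               file.path(outdir, "entropy_weights.csv"))
    res$grey <- grey_relational_table(res$trait_means, cfg$grey$targets,
                                      rho = cfg$grey$rho)
    write_csv_(res$grey, file.path(outdir, "grey_relational.csv"))
    res$pca <- pca_contributions(res$trait_means,
                                 var_target = cfg$pca$var_target)
    write_csv_(data.frame(trait = names(res$pca$contribution),
                          contribution = res$pca$contribution,
                          selected = res$pca$selected),
               file.path(outdir, "pca_contributions.csv"))
    sel <- names(res$pca$contribution)[res$pca$selected]
    res$membership <- membership_scores(res$trait_means[, sel, drop = FALSE],
                                        ori)
    write_csv_(data.frame(germplasm_id = names(res$membership$scores),
                          score = res$membership$scores),
               file.path(outdir, "membership.csv"))
    ch <- cfg$cluster$cut_heights
    cls <- data.frame(
      germplasm_id = rownames(res$trait_means),
      hy_class = hcluster_cut(res$trait_means[, "HY"], ch$hy,
                              linkage = cfg$cluster$linkage),
      fy_class = hcluster_cut(res$trait_means[, "FY"], ch$fy,
                              linkage = cfg$cluster$linkage),
      membership_class = hcluster_cut(res$membership$scores, ch$membership,
                                      linkage = cfg$cluster$linkage)
    )
    res$clusters <- cls
    write_csv_(cls, file.path(outdir, "clusters.csv"))
  }

  if (on("path")) {
    need("path", "trait_means", "traits")
    message("[path] ridge path analysis of HY and FY")
    mt <- res$trait_means
    # FY model: morphological constituents only; HY model may include FY
    # and the hay components
    fy_excl <- c("FY", "HY", "HFR", "HYS", "HYL")
    hy_excl <- c("HY")
    res$path <- list(
      FY = ridge_path(mt[, setdiff(colnames(mt), fy_excl)], mt[, "FY"],
                      k = cfg$ridge$k),
      HY = ridge_path(mt[, setdiff(colnames(mt), hy_excl)], mt[, "HY"],
                      k = cfg$ridge$k)
    )
    for (tg in names(res$path)) {
      p <- res$path[[tg]]
      write_csv_(data.frame(trait = names(p$direct), direct = p$direct,
                            indirect = p$total - p$direct, total = p$total,
                            r_iy = p$r_iy),
                 file.path(outdir, sprintf("path_%s.csv", tolower(tg))))
    }
  }

  if (on("sdm")) {
    need("sdm", "landscape", "simulate")
    message("[sdm] ensemble species distribution model")
    occ <- clean_occurrences(res$occurrences, res$landscape$config$extent)
    occ <- rarefy_occurrences(occ, cfg$sdm$rarefy_resolution,
                              seed = seed_for(4))
    stack <- collinearity_filter(res$landscape$stack,
                                 cfg$sdm$collinearity_threshold)
    bg <- pseudo_absences(stack, occ, seed = seed_for(5))
    res$ensemble <- fit_ensemble(occ, bg, stack,
                                 learners = cfg$sdm$learners,
                                 repeats = cfg$sdm$repeats,
                                 train_fraction = cfg$sdm$train_fraction,
                                 auc_threshold = cfg$sdm$auc_threshold,
                                 seed = seed_for(6))
    res$sdm_stack <- stack
    write_ascii_grid(res$ensemble$consensus,
                     file.path(outdir, "suitability.asc"))
    jsonlite::write_json(
      c(res$ensemble$metrics,
        list(learner_auc = as.list(res$ensemble$learner_auc))),
      file.path(outdir, "sdm_metrics.json"), auto_unbox = TRUE, digits = NA)
    imp <- variable_importance(res$ensemble, stack, seed = seed_for(7))
    res$importance <- imp
    write_csv_(data.frame(variable = names(imp), importance_pct = imp),
               file.path(outdir, "importance.csv"))
    write_csv_(data.frame(learner = rownames(res$ensemble$learner_correlation),
                          round(res$ensemble$learner_correlation, 4)),
               file.path(outdir, "learner_correlation.csv"))
  }

  if (on("geo")) {
    need("geo", "ensemble", "sdm")
    message("[geo] natural-breaks classification and area accounting")
    vals <- res$ensemble$consensus$values
    br <- jenks_breaks(as.vector(vals), k = cfg$geo$breaks_k)
    res$classmap <- classify_suitability(res$ensemble$consensus, br)
    write_ascii_grid(classmap_raster(res$classmap),
                     file.path(outdir, "classified.asc"))
    res$areas <- regional_summary(res$classmap, res$regions)
    write_csv_(as.data.frame(res$areas), file.path(outdir, "region_areas.csv"))
    cent <- class_centroid(res$classmap, c("low", "high"))
    res$centroid <- cent
    jsonlite::write_json(as.list(cent), file.path(outdir, "centroid.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if (on("adapt")) {
    need("adapt", "classmap", "geo")
    need("adapt", "membership", "score")
    message("[adapt] introduction adaptability matrix")
    prof <- suppressWarnings(
      region_profiles(res$ensemble$consensus, res$sdm_stack, res$regions,
                      classmap = res$classmap))
    res$profiles <- prof
    od <- optimal_dissimilarity(prof)
    res$dissimilarity <- od
    ts <- cfg$adapt$trial_site
    trial <- trial_site_profile(res$sdm_stack, ts[["lon"]], ts[["lat"]])
    res$adaptability <- adaptability_matrix(res$membership, prof, trial,
                                            permutations = cfg$adapt$permutations,
                                            seed = seed_for(8))
    A <- res$adaptability
    long <- data.frame(
      germplasm_id = rep(rownames(A$scores), times = ncol(A$scores)),
      region_id = rep(colnames(A$scores), each = nrow(A$scores)),
      score = as.vector(A$scores), class = as.vector(A$classes),
      p_value = rep(A$p_values, each = nrow(A$scores))
    )
    write_csv_(long, file.path(outdir, "adaptability.csv"))
    write_csv_(data.frame(region_id = rownames(A$region_similarity),
                          round(A$region_similarity, 4)),
               file.path(outdir, "region_similarity.csv"))
    write_csv_(data.frame(germplasm_id = names(A$suitable_area_km2),
                          suitable_area_km2 = A$suitable_area_km2),
               file.path(outdir, "suitable_area.csv"))
    jsonlite::write_json(
      list(chosen_dissimilarity = od$chosen,
           rank_correlation = as.list(round(od$rank_correlation, 6))),
      file.path(outdir, "dissimilarity.json"), auto_unbox = TRUE, digits = NA)
  }

  jsonlite::write_json(list(seed = cfg$seed,
                            stages = names(Filter(isTRUE, cfg$stages))),
                       file.path(outdir, "run.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
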