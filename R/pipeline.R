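.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full case-control analysis pipeline
#'
#' Executes, in fixed order: preprocessing (missingness filter, Box-Cox +
#' z-score, kNN imputation), per-variable association screens, incremental
#' ridge-logistic model selection, random-forest importance analysis, PCA
#' similarity embeddings, the spousal shared-environment permutation
#' analysis (when >= 3 spouse pairs exist), and stratified clinical
#' comparisons. Per-stage TSV outputs and a JSON run summary are written
#' to `out_dir`; every output carries the configuration hash and master
#' seed, and a rerun with the same inputs, configuration and seed
#' reproduces identical outputs.
#'
#' @param config a [run_config()].
#' @param freq_path,meta_path input files for [read_cohort()].
#' @param out_dir output directory (created if needed).
#' @return The run summary (also written as `summary.json`), invisibly.
#' @export
run_pipeline <- function(config, freq_path, meta_path, out_dir) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  seeds <- vapply(names(.stage_offsets), function(s) stage_seed(config$master_seed, s),
                  integer(1))

  inp <- .stage("read", read_cohort(freq_path, meta_path))
  table <- inp$table; meta <- inp$meta

  pre <- .stage("preprocess", {
    flt <- filter_missingness(table, config$missingness_threshold)
    tr <- fit_transform(flt$table, bounds = config$boxcox_bounds)
    imp <- knn_impute(tr$table, k = config$knn_k)
    .write_tsv(flt$dropped, file.path(out_dir, "dropped_variables.tsv"))
    write_transform_spec(tr$spec, file.path(out_dir, "transform_spec.json"))
    write_cohort(imp, NULL, file.path(out_dir, "imputed.tsv"))
    list(filtered = flt, transformed = tr, imputed = imp)
  })
  X <- pre$imputed

  assoc <- .stage("associate", {
    dis <- associate_disease(X, meta)
    age_ad <- associate_age(X, meta, subset = "AD")
    age_hc <- associate_age(X, meta, subset = "HC")
    write_association_tsv(dis, file.path(out_dir, "association_disease.tsv"))
    write_association_tsv(rbind(age_ad, age_hc),
                          file.path(out_dir, "association_age.tsv"))
    list(disease = dis, ranking = rank_by_pvalue(dis))
  })

  sel <- .stage("select", {
    mf <- min(config$max_features, length(assoc$ranking))
    curve <- incremental_l2_curve(X, meta$group, assoc$ranking,
                                  age = meta$age, sex = meta$sex,
                                  max_features = mf, k = config$n_folds,
                                  seed = seeds[["select"]],
                                  ridge_lambda = config$ridge_lambda)
    n_star <- select_optimal_n(curve)
    roc <- averaged_roc(curve$fold_scores, curve$fold_labels)
    .write_tsv(curve$curve, file.path(out_dir, "l2_cv_curve.tsv"))
    .write_tsv(roc, file.path(out_dir, "l2_roc.tsv"))
    list(curve = curve, n_star = n_star,
         top = assoc$ranking[seq_len(n_star)])
  })

  rf <- .stage("rf", {
    tuned <- tune_depth_oob(X, meta$group, depth_grid = config$rf_depth_grid,
                            k = config$n_folds, seed = seeds[["rf"]],
                            num_trees = config$rf_trees)
    imp <- gini_ranking(X, meta$group, depth = tuned$depth,
                        num_trees = config$rf_trees, seed = seeds[["rf"]])
    mf <- min(config$max_features, length(imp$ranking))
    curve <- incremental_rf_curve(X, meta$group, imp, max_features = mf,
                                  k = config$n_folds, seed = seeds[["rf"]],
                                  num_trees = config$rf_trees,
                                  depth = tuned$depth)
    .write_tsv(data.frame(variable = imp$ranking,
                          importance = unname(imp$importance)),
               file.path(out_dir, "rf_importance.tsv"))
    .write_tsv(curve$curve, file.path(out_dir, "rf_cv_curve.tsv"))
    jsonlite::write_json(list(depth = tuned$depth,
                              per_fold = tuned$per_fold),
                         file.path(out_dir, "rf_depth.json"),
                         auto_unbox = TRUE, digits = NA)
    list(tuned = tuned, importance = imp, curve = curve,
         n_star = select_optimal_n(curve))
  })

  sim <- .stage("similarity", {
    emb_all <- pca_embed(X)
    sep_all <- group_separation(emb_all, meta$group)
    emb_top <- if (length(sel$top) >= 2) pca_embed(X, sel$top) else NULL
    sep_top <- if (!is.null(emb_top)) group_separation(emb_top, meta$group) else NULL
    .write_tsv(data.frame(subject_id = rownames(emb_all$scores),
                          group = meta$group,
                          pc1 = emb_all$scores[, 1], pc2 = emb_all$scores[, 2]),
               file.path(out_dir, "pca_scores_all.tsv"))
    if (!is.null(emb_top)) {
      .write_tsv(data.frame(subject_id = rownames(emb_top$scores),
                            group = meta$group,
                            pc1 = emb_top$scores[, 1], pc2 = emb_top$scores[, 2]),
                 file.path(out_dir, "pca_scores_top.tsv"))
      .write_tsv(biplot_projection(emb_top, sel$top),
                 file.path(out_dir, "biplot_arrows.tsv"))
    }
    list(sep_all = sep_all$separation,
         sep_top = if (!is.null(sep_top)) sep_top$separation else NA_real_)
  })

  spo <- .stage("spousal", {
    if (!"spouse_id" %in% names(meta) || sum(!is.na(meta$spouse_id)) < 6) {
      NULL
    } else {
      act <- actual_pairings(meta)
      sims <- simulate_pairings(meta, act, config$n_simulated_pairings,
                                age_bin_width = config$age_bin_width,
                                seed = seeds[["spousal"]])
      d_act <- pair_distances(X, act)
      d_sim <- lapply(sims, function(s) pair_distances(X, s))
      cmp_all <- compare_distance_distributions(d_act, d_sim)
      d_act_top <- pair_distances(X, act, sel$top)
      d_sim_top <- lapply(sims, function(s) pair_distances(X, s, sel$top))
      cmp_top <- compare_distance_distributions(d_act_top, d_sim_top)
      scatter <- concordance_pvalue_scatter(X, act, sims,
                                            flag_variables = sel$top,
                                            seed = seeds[["spousal"]])
      .write_tsv(data.frame(pair = seq_along(d_act), distance = d_act),
                 file.path(out_dir, "spousal_distances_actual.tsv"))
      .write_tsv(scatter$table, file.path(out_dir, "spousal_concordance.tsv"))
      list(n_pairs = nrow(act$pairs), all = cmp_all, top = cmp_top,
           slope = scatter$slope)
    }
  })

  cli <- .stage("clinical", {
    fam <- sel$top
    overall <- group_tests(X, meta, fam, "TRUE")
    strat <- list(overall = overall)
    if ("ebv_pos" %in% names(meta)) {
      strat$ebv_pos <- group_tests(X, meta, fam, "ebv_pos")
    }
    tests <- do.call(rbind, strat)
    .write_tsv(tests, file.path(out_dir, "clinical_group_tests.tsv"))
    trend <- NULL
    if ("mmse_band" %in% names(meta) && any(!is.na(meta$mmse_band))) {
      trend <- do.call(rbind, lapply(fam, function(v) {
        grp <- c(list(HC = X$values[meta$group == "HC", v]),
                 lapply(mmse_bands(), function(b) {
                   X$values[meta$group == "AD" & !is.na(meta$mmse_band) &
                              meta$mmse_band == b, v]
                 }))
        tt <- ordered_trend_test(grp)
        data.frame(variable = v, JT = tt$JT, p = tt$p,
                   stringsAsFactors = FALSE)
      }))
      trend$p_bh <- benjamini_hochberg(trend$p)
      .write_tsv(trend, file.path(out_dir, "mmse_trend.tsv"))
    }
    list(tests = tests, trend = trend)
  })

  summary <- list(
    config = unclass(config),
    config_hash = hash,
    stage_seeds = as.list(seeds),
    n_subjects = nrow(X$values),
    n_variables_input = length(table$variable_names),
    n_variables_post_filter = length(pre$filtered$table$variable_names),
    n_variables_post_transform = length(X$variable_names),
    n_missing_cells_input = sum(is.na(table$values)),
    optimal_n_logistic = sel$n_star,
    auc_at_optimal_n = sel$curve$curve$mean_auc[sel$curve$curve$n_features == sel$n_star],
    rf_depth = rf$tuned$depth,
    rf_optimal_n = rf$n_star,
    rf_auc_at_optimal_n = rf$curve$curve$mean_auc[rf$curve$curve$n_features == rf$n_star],
    pca_separation_all = sim$sep_all,
    pca_separation_top = sim$sep_top,
    spousal = if (is.null(spo)) NULL else {
      list(n_pairs = spo$n_pairs,
           p_perm_all = spo$all$p_perm, p_perm_top = spo$top$p_perm,
           concordance_slope = spo$slope)
    }
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(summary)
}
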