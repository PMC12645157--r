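# Depth ordering helper: 0 encodes "unlimited" and sorts after any finite
# depth, so "smallest depth on ties" has a total order.
.depth_key <- function(d) ifelse(d == 0L, Inf, d)

.rf_fit <- function(x, y, depth, num_trees, seed, probability = FALSE,
                    importance = "none") {
  df <- data.frame(.y = factor(y, levels = c(0, 1)), x, check.names = FALSE)
  ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = num_trees, max.depth = depth,
    probability = probability, importance = importance,
    oob.error = TRUE, seed = seed, num.threads = 1
  )
}

#' Tune maximum tree depth by per-fold out-of-bag score
#'
#' For each of k stratified folds, fits a forest at every candidate depth
#' on the training part and records the OOB score (accuracy). The
#' per-fold best depth is the smallest depth attaining the maximal OOB
#' score; the final depth is the mode of the per-fold choices (smallest on
#' multimodality). Depth 0 means unlimited and counts as the largest.
#'
#' @param table a complete [cohort_table()].
#' @param labels case labels.
#' @param depth_grid candidate maximum depths (0 = unlimited).
#' @param k stratified folds.
#' @param seed integer seed.
#' @param num_trees trees per candidate forest.
#' @return List with `depth` (chosen), `per_fold` (data.frame fold ->
#'   chosen depth) and `oob` (fold x depth matrix of OOB scores).
#' @export
tune_depth_oob <- function(table, labels, depth_grid = c(2L, 3L, 4L, 5L, 7L, 10L, 0L),
                           k = 10L, seed = 1L, num_trees = 500L) {
  stopifnot(inherits(table, "cohort_table"))
  if (anyNA(table$values)) stop("table must be complete")
  if (!length(depth_grid)) stop("depth_grid must be non-empty")
  y <- .as_case(labels)
  folds <- stratified_kfold(y, k, seed)
  oob <- matrix(NA_real_, k, length(depth_grid),
                dimnames = list(NULL, paste0("depth", depth_grid)))
  for (f in seq_len(k)) {
    tr <- folds != f
    for (d in seq_along(depth_grid)) {
      fit <- .rf_fit(table$values[tr, , drop = FALSE], y[tr],
                     depth = depth_grid[d], num_trees = num_trees,
                     seed = seed + 1000L * f + d)
      oob[f, d] <- 1 - fit$prediction.error
    }
  }
  if (all(is.na(oob))) stop("all OOB scores undefined")
  per_fold <- vapply(seq_len(k), function(f) {
    best <- which(oob[f, ] == max(oob[f, ]))
    depth_grid[best[which.min(.depth_key(depth_grid[best]))]]
  }, integer(1))
  list(depth = mode_smallest(per_fold),
       per_fold = data.frame(fold = seq_len(k), depth = per_fold),
       oob = oob)
}

#' Most frequent value, smallest on ties
#'
#' Mode of a vector of depth choices; ties are resolved toward the
#' smallest depth, with 0 (unlimited) treated as the largest.
#'
#' @param depths integer vector of per-fold depth choices.
#' @return The modal depth.
#' @export
mode_smallest <- function(depths) {
  tab <- table(depths)
  cand <- as.integer(names(tab)[tab == max(tab)])
  cand[which.min(.depth_key(cand))]
}

#' Gini impurity-decrease importance ranking
#'
#' Trains one forest on the full data at the chosen depth and returns the
#' per-variable impurity-decrease importances normalised to sum 1,
#' descending with name tie-break.
#'
#' @param table a complete [cohort_table()].
#' @param labels case labels.
#' @param depth maximum tree depth (0 = unlimited), e.g. from
#'   [tune_depth_oob()].
#' @param num_trees trees; default 500.
#' @param seed integer seed.
#' @return An object of class `importance_ranking`: `importance` (named,
#'   normalised, in ranked order), `ranking` (variable names) and
#'   `params`.
#' @export
gini_ranking <- function(table, labels, depth = 0L, num_trees = 500L, seed = 1L) {
  stopifnot(inherits(table, "cohort_table"))
  if (anyNA(table$values)) stop("table must be complete")
  zv <- apply(table$values, 2, sd) == 0
  if (any(zv)) warning("zero-variance variable(s): ",
                       paste(colnames(table$values)[zv], collapse = ", "))
  y <- .as_case(labels)
  fit <- .rf_fit(table$values, y, depth = depth, num_trees = num_trees,
                 seed = seed, importance = "impurity")
  imp <- fit$variable.importance
  imp[imp < 0] <- 0
  if (sum(imp) == 0) stop("all importances are zero")
  imp <- imp / sum(imp)
  ord <- order(-imp, names(imp))
  structure(list(importance = imp[ord], ranking = names(imp)[ord],
                 params = list(n_trees = num_trees, depth = depth, seed = seed)),
            class = "importance_ranking")
}

#' Incremental random-forest cross-validated AUC curve
#'
#' For each N, computes the stratified k-fold cross-validated AUC of a
#' probability forest trained on the top-N variables of the importance
#' ranking. Same `cv_curve` container as [incremental_l2_curve()].
#'
#' @param table a complete [cohort_table()].
#' @param labels case labels.
#' @param ranking an `importance_ranking` or a character vector of
#'   variable names, best first.
#' @param max_features largest N.
#' @param k folds.
#' @param seed integer seed.
#' @param num_trees trees per forest.
#' @param depth maximum tree depth (0 = unlimited).
#' @param n_grid optional subset of N values to evaluate (defaults to all
#'   of `1..max_features`); intermediate N are skipped, not interpolated.
#' @return A `cv_curve`.
#' @export
incremental_rf_curve <- function(table, labels, ranking, max_features = 200L,
                                 k = 10L, seed = 1L, num_trees = 500L,
                                 depth = 0L, n_grid = NULL) {
  stopifnot(inherits(table, "cohort_table"))
  if (anyNA(table$values)) stop("table must be complete")
  if (inherits(ranking, "importance_ranking")) ranking <- ranking$ranking
  if (max_features > length(ranking)) {
    warning("max_features exceeds ranking length; truncating to ", length(ranking))
    max_features <- length(ranking)
  }
  n_grid <- n_grid %||% seq_len(max_features)
  n_grid <- sort(unique(n_grid[n_grid <= max_features]))
  y <- .as_case(labels)
  folds <- stratified_kfold(y, k, seed)
  fold_auc <- matrix(NA_real_, k, length(n_grid),
                     dimnames = list(NULL, paste0("N", n_grid)))
  scores_all <- matrix(NA_real_, length(y), length(n_grid))
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    for (i in seq_along(n_grid)) {
      vars <- ranking[seq_len(n_grid[i])]
      fit <- .rf_fit(table$values[tr, vars, drop = FALSE], y[tr],
                     depth = depth, num_trees = num_trees,
                     seed = seed + 1000L * f + i, probability = TRUE)
      pr <- predict(fit, data.frame(table$values[te, vars, drop = FALSE],
                                    check.names = FALSE),
                    num.threads = 1)$predictions[, "1"]
      scores_all[te, i] <- pr
      fold_auc[f, i] <- auc_roc(pr, y[te])
    }
  }
  mean_auc <- colMeans(fold_auc)
  sdv <- apply(fold_auc, 2, sd)
  tq <- qt(0.975, df = k - 1)
  curve <- data.frame(n_features = n_grid, mean_auc = mean_auc,
                      ci_low = mean_auc - tq * sdv / sqrt(k),
                      ci_high = mean_auc + tq * sdv / sqrt(k))
  best <- which.max(mean_auc)
  structure(list(curve = curve, fold_auc = fold_auc,
                 fold_scores = lapply(seq_len(k), function(f) scores_all[folds == f, best]),
                 fold_labels = lapply(seq_len(k), function(f) y[folds == f]),
                 folds = folds, seed = seed, ranking = ranking),
            class = "cv_curve")
}
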