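#' Area under the ROC curve (Mann-Whitney concordance)
#'
#' `(concordant pairs + 0.5 * tied pairs) / (n1 * n0)` computed via ranks,
#' so ties contribute one half.
#'
#' @param scores numeric classifier scores, higher = more case-like.
#' @param labels case indicators (`"AD"`/`"HC"`, logical or 0/1).
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels) {
  y <- .as_case(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified k-fold assignment
#'
#' Subjects of each class are shuffled (seeded) and dealt round-robin to
#' folds, so per-fold class counts differ by at most 1 from exact
#' proportionality. Deterministic given the seed.
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold ids in `1..k`, aligned with `labels`.
#' @export
stratified_kfold <- function(labels, k, seed) {
  y <- .as_case(labels)
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      if (length(idx) < k) {
        stop("class ", cls, " has fewer members (", length(idx),
             ") than folds (", k, ")")
      }
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Ridge-penalised logistic fit via glmnet. `lambda` is on the classical
# penalised-likelihood scale, -loglik(beta) + lambda/2 * ||beta_penalized||^2;
# glmnet's per-observation lambda is lambda / n. Covariate columns listed in
# `unpenalized` carry penalty factor 0.
.ridge_logistic <- function(x, y, lambda, unpenalized = integer()) {
  pf <- rep(1, ncol(x))
  pf[unpenalized] <- 0
  lam <- lambda / nrow(x)
  # descending path ending at the target improves glmnet's warm-start accuracy
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = lam * c(64, 16, 4, 1), penalty.factor = pf,
                        standardize = FALSE)
  function(newx) as.numeric(predict(fit, newx = newx, s = lam, type = "link"))
}

#' Incremental ridge-logistic cross-validated AUC curve
#'
#' For each N in `1..max_features`, fits an L2-penalised logistic
#' regression on the top-N ranked variables plus (unpenalised) age and sex
#' inside each training fold, scores the held-out fold, and records the
#' per-fold AUC. Returns the mean curve with a t-interval across folds.
#' Age and sex are adjustments, never penalised and never counted in N.
#'
#' @param table a complete standardized [cohort_table()].
#' @param labels case labels aligned with the table.
#' @param ranking character vector of variable names, best first (e.g.
#'   from [rank_by_pvalue()]).
#' @param age,sex optional covariates (recommended).
#' @param max_features largest N; truncated with a warning if the ranking
#'   is shorter.
#' @param k folds.
#' @param seed fold-assignment seed.
#' @param ridge_lambda ridge penalty on the penalised log-likelihood scale
#'   (default 1.0).
#' @param nested if `TRUE`, the univariate ranking is recomputed inside
#'   each training fold (honest nested mode, no selection optimism); the
#'   `ranking` argument then defines the candidate pool. The default
#'   (`FALSE`) uses the supplied full-data ranking for every fold.
#' @param rank_fun ranking function for nested mode,
#'   `function(values, labels, age, sex) -> character`; defaults to the
#'   covariate-adjusted univariate logistic screen ordered by
#'   [rank_by_pvalue()].
#' @return An object of class `cv_curve`: data.frame `curve`
#'   (`n_features`, `mean_auc`, `ci_low`, `ci_high`), matrix `fold_auc`
#'   (folds x N), `fold_scores`/`fold_labels` at the best N for ROC
#'   averaging, plus `seed` and `ranking`.
#' @export
incremental_l2_curve <- function(table, labels, ranking, age = NULL, sex = NULL,
                                 max_features = 200L, k = 10L, seed = 1L,
                                 ridge_lambda = 1.0, nested = FALSE,
                                 rank_fun = NULL) {
  stopifnot(inherits(table, "cohort_table"))
  v <- table$values
  if (anyNA(v)) stop("table must be complete (impute first)")
  missing_vars <- setdiff(ranking, colnames(v))
  if (length(missing_vars)) stop("ranking contains unknown variables: ",
                                 paste(utils::head(missing_vars, 5), collapse = ", "))
  if (max_features > length(ranking)) {
    warning("max_features exceeds ranking length; truncating to ", length(ranking))
    max_features <- length(ranking)
  }
  y <- .as_case(labels)
  cov <- NULL
  if (!is.null(age)) cov <- cbind(cov, zage = as.numeric(scale(as.numeric(age))))
  if (!is.null(sex)) cov <- cbind(cov, sexM = as.numeric(sex == "M"))
  ncov <- if (is.null(cov)) 0L else ncol(cov)
  folds <- stratified_kfold(y, k, seed)

  if (nested && is.null(rank_fun)) {
    rank_fun <- function(values, labels, age, sex) {
      recs <- do.call(rbind, lapply(colnames(values), function(vn) {
        fit_logistic_association(values[, vn], labels, age = age, sex = sex,
                                 variable = vn)
      }))
      rank_by_pvalue(recs)
    }
  }

  fold_auc <- matrix(NA_real_, k, max_features,
                     dimnames = list(NULL, paste0("N", seq_len(max_features))))
  scores_all <- matrix(NA_real_, length(y), max_features)
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    fold_rank <- if (nested) {
      rank_fun(v[tr, ranking, drop = FALSE], y[tr],
               if (is.null(age)) NULL else age[tr],
               if (is.null(sex)) NULL else sex[tr])
    } else {
      ranking
    }
    for (N in seq_len(max_features)) {
      xs <- v[, fold_rank[seq_len(N)], drop = FALSE]
      x <- if (is.null(cov)) xs else cbind(xs, cov)
      if (ncol(x) == 1L) x <- cbind(x, .const = 0)  # glmnet needs >= 2 columns
      scorer <- .ridge_logistic(x[tr, , drop = FALSE], y[tr], ridge_lambda,
                                unpenalized = if (ncov) N + seq_len(ncov) else integer())
      sc <- scorer(x[te, , drop = FALSE])
      scores_all[te, N] <- sc
      fold_auc[f, N] <- auc_roc(sc, y[te])
    }
  }
  mean_auc <- colMeans(fold_auc)
  sdv <- apply(fold_auc, 2, sd)
  tq <- qt(0.975, df = k - 1)
  curve <- data.frame(n_features = seq_len(max_features),
                      mean_auc = mean_auc,
                      ci_low = mean_auc - tq * sdv / sqrt(k),
                      ci_high = mean_auc + tq * sdv / sqrt(k))
  best <- which.max(mean_auc)
  structure(list(curve = curve, fold_auc = fold_auc,
                 fold_scores = lapply(seq_len(k), function(f) scores_all[folds == f, best]),
                 fold_labels = lapply(seq_len(k), function(f) y[folds == f]),
                 folds = folds, seed = seed,
                 ranking = ranking[seq_len(max_features)]),
            class = "cv_curve")
}

#' Smallest N attaining the maximum mean cross-validated AUC
#'
#' @param curve a `cv_curve`.
#' @return Integer N*.
#' @export
select_optimal_n <- function(curve) {
  stopifnot(inherits(curve, "cv_curve"))
  m <- curve$curve$mean_auc
  if (!length(m)) stop("empty curve")
  curve$curve$n_features[which.max(m)]
}

#' Vertically averaged ROC curve across folds
#'
#' Per-fold ROC curves are evaluated as step functions on a fixed
#' false-positive-rate grid and averaged; the 95% band is a normal
#' approximation from the across-fold SD of the true-positive rate.
#' Folds containing a single class are skipped with a warning.
#'
#' @param fold_scores list of per-fold score vectors.
#' @param fold_labels list of matching label vectors.
#' @param grid FPR grid in `[0, 1]`.
#' @return A data.frame `fpr`, `tpr`, `ci_low`, `ci_high` with attribute
#'   `"auc"` (trapezoidal AUC of the averaged curve).
#' @export
averaged_roc <- function(fold_scores, fold_labels, grid = seq(0, 1, by = 0.01)) {
  stopifnot(length(fold_scores) == length(fold_labels),
            length(fold_scores) >= 2L)
  tprs <- list()
  for (f in seq_along(fold_scores)) {
    y <- .as_case(fold_labels[[f]])
    if (length(unique(y)) < 2L) {
      warning("fold ", f, " has a single class; skipped")
      next
    }
    s <- fold_scores[[f]]
    ord <- order(s, decreasing = TRUE)
    tp <- cumsum(y[ord] == 1) / sum(y == 1)
    fp <- cumsum(y[ord] == 0) / sum(y == 0)
    # step-function TPR at each grid FPR: max TPR with FPR <= grid value
    tprs[[length(tprs) + 1L]] <- vapply(grid, function(g) {
      ok <- fp <= g + 1e-12
      if (any(ok)) max(tp[ok]) else 0
    }, numeric(1))
  }
  if (length(tprs) < 2L) stop("fewer than 2 usable folds")
  m <- do.call(rbind, tprs)
  mu <- colMeans(m)
  sdv <- apply(m, 2, sd)
  half <- qnorm(0.975) * sdv / sqrt(nrow(m))
  out <- data.frame(fpr = grid, tpr = mu,
                    ci_low = pmax(0, mu - half), ci_high = pmin(1, mu + half))
  attr(out, "auc") <- sum(diff(grid) * (mu[-1] + mu[-length(mu)]) / 2)
  out
}
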