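#' Pipeline run configuration
#'
#' Collects every tunable parameter of the pipeline in one validated list.
#' Defaults mirror the analysis conventions of the package: >20%%
#' missingness filter, k = 3 imputation neighbours, Box-Cox lambda bounds
#' (-5, 5), stratified 10-fold cross-validation, and feature sweeps up to
#' 200 variables.
#'
#' @param missingness_threshold variables with missing fraction strictly
#'   greater than this are dropped. In (0, 1); default 0.20.
#' @param knn_k neighbours for kNN imputation (>= 1); default 3.
#' @param boxcox_bounds length-2 numeric, lambda search bounds; default
#'   c(-5, 5).
#' @param n_folds cross-validation folds (>= 2); default 10.
#' @param max_features upper end of the incremental feature sweep;
#'   default 200.
#' @param ridge_lambda ridge penalty on the penalised log-likelihood scale
#'   (see [incremental_l2_curve()]); default 1.0.
#' @param rf_depth_grid candidate maximum tree depths; 0 means unlimited.
#' @param rf_trees trees per forest; default 500.
#' @param n_simulated_pairings simulated spousal pairing sets; default 1000.
#' @param age_bin_width bin width (years) for age-structure-preserving
#'   re-pairings; default 10.
#' @param master_seed master seed expanded into per-stage seeds by
#'   [stage_seed()].
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(missingness_threshold = 0.20,
                       knn_k = 3L,
                       boxcox_bounds = c(-5, 5),
                       n_folds = 10L,
                       max_features = 200L,
                       ridge_lambda = 1.0,
                       rf_depth_grid = c(2L, 3L, 4L, 5L, 7L, 10L, 0L),
                       rf_trees = 500L,
                       n_simulated_pairings = 1000L,
                       age_bin_width = 10,
                       master_seed = 1L) {
  cfg <- structure(
    list(missingness_threshold = missingness_threshold,
         knn_k = as.integer(knn_k),
         boxcox_bounds = as.numeric(boxcox_bounds),
         n_folds = as.integer(n_folds),
         max_features = as.integer(max_features),
         ridge_lambda = ridge_lambda,
         rf_depth_grid = as.integer(rf_depth_grid),
         rf_trees = as.integer(rf_trees),
         n_simulated_pairings = as.integer(n_simulated_pairings),
         age_bin_width = age_bin_width,
         master_seed = as.integer(master_seed)),
    class = "run_config"
  )
  validate_config(cfg)
  cfg
}

#' Validate a run configuration
#' @param cfg a `run_config`.
#' @return `cfg` invisibly; errors on invariant violations.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!(cfg$missingness_threshold > 0 && cfg$missingness_threshold < 1)) {
    stop("missingness_threshold must be in (0, 1)")
  }
  if (cfg$knn_k < 1L) stop("knn_k must be >= 1")
  if (length(cfg$boxcox_bounds) != 2L || cfg$boxcox_bounds[1] >= cfg$boxcox_bounds[2]) {
    stop("boxcox_bounds must be an increasing pair")
  }
  if (cfg$n_folds < 2L) stop("n_folds must be >= 2")
  if (cfg$max_features < 1L) stop("max_features must be >= 1")
  if (cfg$ridge_lambda < 0) stop("ridge_lambda must be >= 0")
  if (!length(cfg$rf_depth_grid)) stop("rf_depth_grid must be non-empty")
  if (cfg$n_simulated_pairings < 1L) stop("n_simulated_pairings must be >= 1")
  invisible(cfg)
}

#' Hash a configuration for provenance stamping
#'
#' MD5 of the canonical JSON serialisation; written into every pipeline
#' output so results can be traced to the exact configuration.
#'
#' @param cfg a `run_config`.
#' @return A 32-character hex string.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(cfg), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}
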