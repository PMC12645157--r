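#' PCA embedding of immune-phenotypic similarity
#'
#' Eigen-decomposition of the covariance of the column-standardized
#' selected variables (equivalent, up to sign, to principal coordinates
#' analysis of the Euclidean distance matrix between subjects). A
#' deterministic sign convention is applied: on each component, the
#' variable with the largest |loading| has a positive loading.
#'
#' @param table a complete [cohort_table()].
#' @param variables variable subset to embed (default all); must have >= 2
#'   members and no zero-variance column.
#' @return An object of class `pca_embedding`: `scores` (subjects x
#'   components), `loadings` (variables x components), `var_share`
#'   (variance shares summing to 1), `variables`.
#' @export
pca_embed <- function(table, variables = NULL) {
  stopifnot(inherits(table, "cohort_table"))
  v <- table$values
  if (anyNA(v)) stop("table must be complete")
  variables <- variables %||% colnames(v)
  if (length(variables) < 2L) stop("need at least 2 variables")
  x <- v[, variables, drop = FALSE]
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) stop("zero-variance variable(s): ",
                          paste(variables[sds == 0], collapse = ", "))
  x <- scale(x)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  # sign convention per component
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  structure(list(scores = pc$x, loadings = pc$rotation,
                 var_share = pc$sdev^2 / sum(pc$sdev^2),
                 variables = variables),
            class = "pca_embedding")
}

#' Biplot arrow coordinates for selected markers
#'
#' Projects marker loadings onto the PC1/PC2 plane, scaled for overlay on
#' a score plot. Arrow length is proportional to the loading norm.
#'
#' @param embedding a [pca_embed()] result.
#' @param markers variable names to project; must be embedded variables.
#' @param scale multiplier applied to the loadings.
#' @return A data.frame `marker`, `pc1`, `pc2`.
#' @export
biplot_projection <- function(embedding, markers, scale = 1) {
  stopifnot(inherits(embedding, "pca_embedding"))
  missing_m <- setdiff(markers, rownames(embedding$loadings))
  if (length(missing_m)) stop("marker(s) not in embedding: ",
                              paste(missing_m, collapse = ", "))
  L <- embedding$loadings[markers, 1:2, drop = FALSE] * scale
  data.frame(marker = markers, pc1 = L[, 1], pc2 = L[, 2],
             stringsAsFactors = FALSE)
}

#' Case-control separation along principal components
#'
#' Per-component group histograms (shared breaks) and standardized mean
#' differences; the overall separation statistic is the Euclidean norm of
#' the per-component standardized differences over the first `n_pc`
#' components. Invariant to PC sign flips.
#'
#' @param embedding a [pca_embed()] result (or a score matrix).
#' @param labels two-group labels aligned with the scores.
#' @param n_pc number of leading components (default 2).
#' @param breaks histogram bin count passed to [graphics::hist()].
#' @return List with `smd` (per-PC standardized mean difference),
#'   `separation` (norm over the first `n_pc`), and `histograms` (per PC,
#'   per group counts and shared breaks).
#' @export
group_separation <- function(embedding, labels, n_pc = 2L, breaks = 20L) {
  scores <- if (inherits(embedding, "pca_embedding")) embedding$scores else as.matrix(embedding)
  y <- .as_case(labels)
  if (length(unique(y)) < 2L) stop("need two groups")
  n_pc <- min(n_pc, ncol(scores))
  smds <- numeric(n_pc)
  hists <- vector("list", n_pc)
  for (j in seq_len(n_pc)) {
    s <- scores[, j]
    smds[j] <- smd(s, y == 1)
    br <- seq(min(s), max(s), length.out = breaks + 1L)
    hists[[j]] <- list(
      breaks = br,
      case = hist(s[y == 1], breaks = br, plot = FALSE)$counts,
      control = hist(s[y == 0], breaks = br, plot = FALSE)$counts
    )
  }
  names(smds) <- colnames(scores)[seq_len(n_pc)]
  list(smd = smds, separation = sqrt(sum(smds^2)), histograms = hists)
}
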