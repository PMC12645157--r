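`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' that seeded helpers do not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic expansion of the master seed into per-stage seeds.
# Offsets are fixed and documented so individual stages are reproducible
# without running their predecessors.
.stage_offsets <- c(
  simulate = 1L, preprocess = 2L, associate = 3L, select = 4L,
  rf = 5L, similarity = 6L, spousal = 7L, clinical = 8L
)

#' Derive a per-stage seed from the master seed
#'
#' @param master integer master seed.
#' @param stage one of `"simulate"`, `"preprocess"`, `"associate"`,
#'   `"select"`, `"rf"`, `"similarity"`, `"spousal"`, `"clinical"`.
#' @return An integer seed, `master * 100 + offset(stage)`.
#' @export
stage_seed <- function(master, stage) {
  stage <- match.arg(stage, names(.stage_offsets))
  as.integer(master) * 100L + .stage_offsets[[stage]]
}

#' Sample standardized mean difference (pooled within-group SD)
#' @keywords internal
smd <- function(x, g) {
  g <- as.logical(g)
  x1 <- x[g]; x0 <- x[!g]
  sp <- sqrt(((length(x1) - 1) * var(x1) + (length(x0) - 1) * var(x0)) /
               (length(x1) + length(x0) - 2))
  (mean(x1) - mean(x0)) / sp
}
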