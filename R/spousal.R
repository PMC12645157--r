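#' Extract actual spousal pairings from metadata
#'
#' Each symmetric spouse link becomes one pair, ordered AD member first.
#'
#' @param meta validated metadata data.frame with `spouse_id`.
#' @return A `pairing_set`: list with `pairs` (data.frame `a`, `b`),
#'   `kind = "actual"`, `constraint = NULL`, `seed = NA`.
#' @export
actual_pairings <- function(meta) {
  if (!"spouse_id" %in% names(meta)) stop("metadata has no spouse_id column")
  meta <- validate_subjects(meta)
  ad <- meta$group == "AD" & !is.na(meta$spouse_id)
  pairs <- data.frame(a = meta$subject_id[ad], b = meta$spouse_id[ad],
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, kind = "actual", constraint = NULL, seed = NA),
            class = "pairing_set")
}

#' @export
#' @method print pairing_set
print.pairing_set <- function(x, ...) {
  cat(sprintf("pairing_set (%s): %d pairs\n", x$kind, nrow(x$pairs)))
  invisible(x)
}

#' Per-pair Euclidean distance over selected variables
#'
#' @param table a complete standardized [cohort_table()].
#' @param pairing a `pairing_set`.
#' @param variables variable subset (default all).
#' @return Numeric vector of distances, one per pair.
#' @export
pair_distances <- function(table, pairing, variables = NULL) {
  stopifnot(inherits(table, "cohort_table"), inherits(pairing, "pairing_set"))
  variables <- variables %||% table$variable_names
  ids <- table$subject_ids
  missing_s <- setdiff(c(pairing$pairs$a, pairing$pairs$b), ids)
  if (length(missing_s)) stop("pair member(s) missing from table: ",
                              paste(missing_s, collapse = ", "))
  xa <- table$values[pairing$pairs$a, variables, drop = FALSE]
  xb <- table$values[pairing$pairs$b, variables, drop = FALSE]
  sqrt(rowSums((xa - xb)^2))
}

#' Constraint-preserving simulated spousal pairings
#'
#' Generates randomized re-pairings of the same subjects that preserve
#' (a) the multiset of pair sex-compositions exactly, and (b) the
#' within-pair age-gap structure approximately, by permuting the `b`-side
#' partners only within strata of identical (partner sex, partner age
#' bin). Within each stratum a derangement is attempted (up to 20
#' redraws) so simulated pairs differ from actual ones; singleton strata
#' make some actual pairs unavoidable, and the count of such unchanged
#' pairs is recorded in each set's `n_unchanged`. Deterministic given the
#' seed (set s uses `seed + s`).
#'
#' @param meta validated metadata (for sex and age of the partners).
#' @param actual the actual `pairing_set`.
#' @param n_sets number of simulated sets.
#' @param age_bin_width age bin width in years (default 10).
#' @param seed integer base seed.
#' @return A list of `pairing_set`s with `kind = "simulated"`.
#' @export
simulate_pairings <- function(meta, actual, n_sets, age_bin_width = 10,
                              seed = 1L) {
  stopifnot(inherits(actual, "pairing_set"))
  pairs <- actual$pairs
  if (nrow(pairs) < 2L) stop("need at least 2 pairs to re-pair")
  idx <- match(pairs$b, meta$subject_id)
  if (anyNA(idx)) stop("pair partner(s) absent from metadata")
  stratum <- paste(meta$sex[idx],
                   floor(meta$age[idx] / age_bin_width), sep = "/")
  constraint <- list(age_bin_width = age_bin_width,
                     strata = table(stratum))
  lapply(seq_len(n_sets), function(s) {
    b_new <- with_seed(seed + s, {
      out <- pairs$b
      for (st in unique(stratum)) {
        members <- which(stratum == st)
        if (length(members) < 2L) next
        perm <- sample(members)
        tries <- 0L
        while (any(perm == members) && tries < 20L) {
          perm <- sample(members)
          tries <- tries + 1L
        }
        out[members] <- pairs$b[perm]
      }
      out
    })
    if (anyDuplicated(b_new)) stop("internal error: subject reused within a set")
    structure(list(pairs = data.frame(a = pairs$a, b = b_new,
                                      stringsAsFactors = FALSE),
                   kind = "simulated", constraint = constraint,
                   seed = seed + s,
                   n_unchanged = sum(b_new == pairs$b)),
              class = "pairing_set")
  })
}

#' Compare actual and simulated spousal distance distributions
#'
#' Two tests of shared-environment concordance: a two-sided Mann-Whitney
#' U of the actual distances against all simulated distances pooled, and a
#' permutation p-value, `(1 + #{sets with median <= actual median}) /
#' (1 + n_sets)` - small when actual spouses are more similar than the
#' constraint-preserving null allows.
#'
#' @param actual_distances numeric vector from [pair_distances()] on the
#'   actual pairing.
#' @param simulated_distances list of numeric vectors, one per simulated
#'   set.
#' @return List: `u_stat`, `p_mw`, `p_perm`, `median_actual`,
#'   `median_simulated` (grand median).
#' @export
compare_distance_distributions <- function(actual_distances, simulated_distances) {
  if (!length(actual_distances) || !length(simulated_distances)) {
    stop("both distance sets must be non-empty")
  }
  pooled <- unlist(simulated_distances)
  mw <- suppressWarnings(wilcox.test(actual_distances, pooled, exact = FALSE))
  med_a <- median(actual_distances)
  med_s <- vapply(simulated_distances, median, numeric(1))
  list(u_stat = unname(mw$statistic),
       p_mw = mw$p.value,
       p_perm = (1 + sum(med_s <= med_a)) / (1 + length(med_s)),
       median_actual = med_a,
       median_simulated = median(pooled))
}

#' Per-variable spousal concordance p-values, actual vs simulated
#'
#' For every variable, computes a Spearman rank-correlation test p-value
#' between partner values across the actual pairs (`p_actual`), and the
#' geometric mean (Fisher-combined, back-transformed) of the same
#' statistic over the simulated sets (`p_simulated`). Partner order is
#' randomized once per pair (seeded) and reused across all sets, so
#' ordering artefacts cancel. Constant variables are excluded with a
#' warning. A least-squares regression of `-log10 p_actual` on
#' `-log10 p_simulated` summarises the scatter against the identity
#' (null) line.
#'
#' @param table a complete standardized [cohort_table()].
#' @param actual the actual `pairing_set`.
#' @param simulated list of simulated `pairing_set`s.
#' @param variables variables to test (default all).
#' @param flag_variables optional character vector (e.g. the
#'   disease-associated set) marked TRUE in the output.
#' @param seed seed for the per-pair partner-order randomization.
#' @return List with `table` (data.frame `variable`, `p_actual`,
#'   `p_simulated`, `flagged`), `slope`, `intercept`.
#' @export
concordance_pvalue_scatter <- function(table, actual, simulated,
                                       variables = NULL,
                                       flag_variables = character(),
                                       seed = 1L) {
  stopifnot(inherits(table, "cohort_table"))
  variables <- variables %||% table$variable_names
  np <- nrow(actual$pairs)
  if (np < 3L) stop("need at least 3 pairs")
  missing_v <- setdiff(variables, table$variable_names)
  if (length(missing_v)) stop("variable(s) missing from table: ",
                              paste(missing_v, collapse = ", "))
  swap <- with_seed(seed, runif(np) < 0.5)

  spearman_p <- function(a, b) {
    suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE)$p.value)
  }
  pair_values <- function(pairing, v) {
    a <- table$values[pairing$pairs$a, v]
    b <- table$values[pairing$pairs$b, v]
    a2 <- ifelse(swap, b, a)
    b2 <- ifelse(swap, a, b)
    list(a = a2, b = b2)
  }

  rows <- lapply(variables, function(v) {
    col <- table$values[, v]
    if (sd(col) == 0) {
      warning("constant variable excluded: ", v)
      return(NULL)
    }
    av <- pair_values(actual, v)
    pa <- spearman_p(av$a, av$b)
    ps <- vapply(simulated, function(s) {
      sv <- pair_values(s, v)
      spearman_p(sv$a, sv$b)
    }, numeric(1))
    data.frame(variable = v, p_actual = pa,
               p_simulated = exp(mean(log(pmax(ps, 1e-300)))),
               flagged = v %in% flag_variables,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) < 2L) stop("too few usable variables")
  fit <- lm(I(-log10(tab$p_actual)) ~ I(-log10(tab$p_simulated)))
  list(table = tab, slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]))
}
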