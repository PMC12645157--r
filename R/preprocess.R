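#' Drop variables exceeding a missingness threshold
#'
#' A variable is kept iff its missing fraction is less than or equal to the
#' threshold; strictly greater is dropped (so at the default 0.20, a
#' variable missing in exactly 20% of subjects survives). Subjects are
#' never dropped by this step.
#'
#' @param table a [cohort_table()].
#' @param threshold maximum tolerated missing fraction, in (0, 1).
#' @return A list with `table` (filtered) and `dropped`, a data.frame of
#'   dropped variables with their missing fractions.
#' @export
filter_missingness <- function(table, threshold = 0.20) {
  stopifnot(inherits(table, "cohort_table"))
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  v <- table$values
  if (!nrow(v) || !ncol(v)) stop("empty cohort table")
  frac <- colMeans(is.na(v))
  drop <- frac > threshold
  dropped <- data.frame(variable = colnames(v)[drop],
                        missing_fraction = unname(frac[drop]),
                        stringsAsFactors = FALSE)
  list(table = cohort_table(v[, !drop, drop = FALSE], provenance = table$provenance),
       dropped = dropped)
}

# Box-Cox profile log-likelihood for strictly positive x at lambda.
.boxcox_loglik <- function(x, lambda) {
  n <- length(x)
  y <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
  -n / 2 * log(mean((y - mean(y))^2)) + (lambda - 1) * sum(log(x))
}

#' Estimate the Box-Cox lambda by profile log-likelihood
#'
#' Maximises the Box-Cox profile log-likelihood over the bounded interval
#' (default -5 to 5) with [stats::optimize()]; the returned value is
#' clamped to the bounds.
#'
#' @param values numeric vector, non-missing and strictly positive (apply
#'   the shift first; see [boxcox_shift()]).
#' @param bounds length-2 numeric search interval.
#' @return The estimated lambda.
#' @export
fit_boxcox_lambda <- function(values, bounds = c(-5, 5)) {
  x <- values[!is.na(values)]
  if (length(x) < 10L) stop("need at least 10 non-missing values to fit lambda")
  if (any(x <= 0)) stop("values must be strictly positive after shifting")
  if (var(x) == 0) {
    warning("zero variance; returning lambda = 1")
    return(1)
  }
  opt <- optimize(function(l) .boxcox_loglik(x, l),
                  interval = bounds, maximum = TRUE, tol = 1e-6)
  lam <- opt$maximum
  # optimize never returns the exact endpoints; snap when the boundary is
  # at least as good as the interior optimum
  for (b in bounds) {
    if (.boxcox_loglik(x, b) >= opt$objective) lam <- b
  }
  min(max(lam, bounds[1]), bounds[2])
}

#' Positivity shift for a frequency variable
#'
#' `1 - min(x)` when `min(x) <= 0`, else 0: the smallest unit shift that
#' guarantees strict positivity for Box-Cox.
#'
#' @param values numeric vector (missing allowed).
#' @return The shift.
#' @export
boxcox_shift <- function(values) {
  m <- min(values, na.rm = TRUE)
  if (m <= 0) 1 - m else 0
}

#' Apply a Box-Cox transform
#'
#' `y = ((x + shift)^lambda - 1) / lambda` for `lambda != 0`;
#' `y = log(x + shift)` for `lambda = 0`. Missing stays missing.
#'
#' @param values numeric vector.
#' @param lambda Box-Cox exponent.
#' @param shift additive shift applied before transforming.
#' @return Transformed vector of the same length.
#' @export
apply_boxcox <- function(values, lambda, shift = 0) {
  x <- values + shift
  bad <- !is.na(x) & x <= 0
  if (any(bad)) {
    nm <- names(values)[bad] %||% which(bad)
    stop("non-positive shifted value at position(s): ",
         paste(utils::head(nm, 5), collapse = ", "))
  }
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

#' z-score a vector
#'
#' Centers and scales by the sample mean and SD of the non-missing
#' entries; missing stays missing.
#'
#' @param values numeric vector with at least 2 non-missing values.
#' @return List with `values` (z-scored), `mean`, `sd`.
#' @export
standardize <- function(values) {
  obs <- values[!is.na(values)]
  if (length(obs) < 2L) stop("need at least 2 non-missing values")
  m <- mean(obs); s <- sd(obs)
  if (s == 0) stop("zero variance; variable should be excluded")
  list(values = (values - m) / s, mean = m, sd = s)
}

#' Fit per-variable Box-Cox + z-score transforms on a cohort table
#'
#' Fits lambda, shift, mean and SD per variable on all subjects pooled
#' (cases and controls together) and applies them, producing a table whose
#' observed entries have mean 0 and SD 1 per variable. Variables with zero
#' variance or fewer than 10 observed values are dropped with a warning.
#'
#' @param table a [cohort_table()] of raw frequencies.
#' @param bounds lambda search bounds.
#' @return List with `table` (transformed `cohort_table`, attribute
#'   `standardized = TRUE`) and `spec`, a `transform_spec` data.frame with
#'   columns `variable`, `lambda`, `shift`, `mean`, `sd`, `fitted_on`.
#' @export
fit_transform <- function(table, bounds = c(-5, 5)) {
  v <- table$values
  keep <- logical(ncol(v))
  spec <- vector("list", ncol(v))
  out <- v
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    obs <- x[!is.na(x)]
    if (length(obs) < 10L || length(unique(obs)) < 2L) {
      warning("dropping degenerate variable ", colnames(v)[j])
      next
    }
    shift <- boxcox_shift(x)
    lam <- fit_boxcox_lambda(obs + shift, bounds = bounds)
    y <- apply_boxcox(x, lam, shift)
    z <- standardize(y)
    out[, j] <- z$values
    keep[j] <- TRUE
    spec[[j]] <- data.frame(variable = colnames(v)[j], lambda = lam,
                            shift = shift, mean = z$mean, sd = z$sd,
                            fitted_on = length(obs), stringsAsFactors = FALSE)
  }
  spec <- do.call(rbind, spec[keep])
  tab <- cohort_table(out[, keep, drop = FALSE], provenance = table$provenance,
                      standardized = TRUE)
  list(table = tab, spec = structure(spec, class = c("transform_spec", "data.frame")))
}

#' Reapply a fitted transform spec to new data
#'
#' @param table a raw-scale [cohort_table()] containing the spec's
#'   variables.
#' @param spec a `transform_spec` from [fit_transform()].
#' @return A transformed `cohort_table`.
#' @export
apply_transform <- function(table, spec) {
  v <- table$values[, spec$variable, drop = FALSE]
  for (j in seq_len(nrow(spec))) {
    y <- apply_boxcox(v[, j], spec$lambda[j], spec$shift[j])
    v[, j] <- (y - spec$mean[j]) / spec$sd[j]
  }
  cohort_table(v, provenance = table$provenance, standardized = TRUE)
}

#' Write / read a transform spec as JSON
#' @param spec a `transform_spec`.
#' @param path JSON path.
#' @return `path` invisibly (write) or the spec (read).
#' @export
write_transform_spec <- function(spec, path) {
  jsonlite::write_json(as.data.frame(spec), path, digits = NA)
  invisible(path)
}

#' @rdname write_transform_spec
#' @export
read_transform_spec <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = c("transform_spec", "data.frame"))
}

#' k-nearest-neighbour imputation of a standardized cohort table
#'
#' Each missing cell is replaced by the aggregate (median by default) of
#' that variable's values in the k nearest subjects, using Euclidean
#' distance over the variables observed in both subjects, rescaled by
#' `n_variables / n_shared` (standard partial-distance scaling). Ties in
#' neighbour distance are broken by subject-id order for determinism. If
#' fewer than k donors observe the variable, the available donors are used
#' with a warning.
#'
#' @param table a standardized [cohort_table()] (see [fit_transform()]);
#'   raw-scale input is refused unless `check_scale = FALSE`.
#' @param k number of donor neighbours (default 3).
#' @param aggregate `"median"` (default) or `"mean"`.
#' @param check_scale verify the table looks z-scored (column means near
#'   0) before imputing.
#' @return A complete `cohort_table`; observed cells are unchanged.
#' @export
knn_impute <- function(table, k = 3L, aggregate = c("median", "mean"),
                       check_scale = TRUE) {
  stopifnot(inherits(table, "cohort_table"))
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "median") median else mean
  v <- table$values
  if (!anyNA(v)) return(table)
  if (check_scale && !isTRUE(attr(table, "standardized"))) {
    mu <- abs(colMeans(v, na.rm = TRUE))
    if (any(mu > 0.5)) {
      stop("table does not look standardized (|column mean| > 0.5); ",
           "transform first or set check_scale = FALSE")
    }
  }
  n <- nrow(v); p <- ncol(v)
  obs <- !is.na(v)
  v0 <- v; v0[!obs] <- 0
  sq <- v0^2
  shared <- obs %*% t(obs)                       # shared observed counts
  cross <- sq %*% t(obs)                         # sum x_i^2 over shared
  d2 <- (cross + t(cross) - 2 * v0 %*% t(v0)) / shared * p
  d2[shared == 0] <- Inf
  diag(d2) <- Inf
  d2[d2 < 0] <- 0                                # numerical noise

  out <- v
  for (i in which(rowSums(!obs) > 0)) {
    if (all(is.infinite(d2[i, ]))) {
      stop("subject ", rownames(v)[i], " shares no observed variable with any donor")
    }
    ord <- order(d2[i, ], seq_len(n))            # distance, then id order
    for (j in which(!obs[i, ])) {
      donors <- ord[obs[ord, j] & is.finite(d2[i, ord])]
      if (!length(donors)) {
        stop("no donor observes variable ", colnames(v)[j],
             " for subject ", rownames(v)[i])
      }
      if (length(donors) < k) {
        warning(sprintf("only %d donor(s) available for subject %s, variable %s",
                        length(donors), rownames(v)[i], colnames(v)[j]))
      }
      out[i, j] <- agg(v[donors[seq_len(min(k, length(donors)))], j])
    }
  }
  cohort_table(out, provenance = table$provenance,
               standardized = isTRUE(attr(table, "standardized")))
}
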