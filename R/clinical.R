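#' Mann-Whitney U test
#'
#' U statistic for `x` versus `y` (number of `(x_i, y_j)` pairs with
#' `x_i > y_j`, ties counted half). The p-value is exact for combined
#' n <= 12 without ties and a normal approximation with tie correction
#' (and continuity correction) otherwise.
#'
#' @param x,y numeric samples.
#' @return List with `U` and two-sided `p`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  exact <- (length(x) + length(y) <= 12L) && !anyDuplicated(c(x, y))
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment with monotonicity enforcement, mapped
#' back to the input order.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Kruskal-Wallis global test with BH-adjusted pairwise follow-up
#'
#' Tie-corrected Kruskal-Wallis H with chi-square p, followed by all
#' pairwise Mann-Whitney tests with Benjamini-Hochberg correction within
#' the variable.
#'
#' @param groups list of >= 3 non-empty numeric samples (names used for
#'   the pairwise matrix).
#' @return List with `H`, `p`, and `pairwise` (symmetric matrix of
#'   BH-adjusted p-values, unit diagonal).
#' @export
kruskal_wallis_pairwise <- function(groups) {
  if (length(groups) < 3L) stop("need >= 3 groups (use mann_whitney_u for 2)")
  if (any(!lengths(groups))) stop("all groups must be non-empty")
  names(groups) <- names(groups) %||% paste0("g", seq_along(groups))
  kw <- kruskal.test(groups)
  k <- length(groups)
  combs <- combn(k, 2)
  praw <- apply(combs, 2, function(ij) {
    mann_whitney_u(groups[[ij[1]]], groups[[ij[2]]])$p
  })
  padj <- benjamini_hochberg(praw)
  m <- diag(1, k)
  dimnames(m) <- list(names(groups), names(groups))
  for (c_i in seq_len(ncol(combs))) {
    m[combs[1, c_i], combs[2, c_i]] <- padj[c_i]
    m[combs[2, c_i], combs[1, c_i]] <- padj[c_i]
  }
  list(H = unname(kw$statistic), p = kw$p.value, pairwise = m)
}

#' Disease-by-stratum interaction test
#'
#' Linear model of the immune variable on disease, stratum, their
#' product, age and sex; reports the Wald p-value of the product term.
#' All four disease x stratum cells must be non-empty.
#'
#' @param values numeric immune variable.
#' @param disease case labels.
#' @param stratum two-level stratification (e.g. serostatus), logical or
#'   factor-like.
#' @param age,sex optional covariates.
#' @return List with `estimate` (interaction coefficient) and `p`.
#' @export
interaction_test <- function(values, disease, stratum, age = NULL, sex = NULL) {
  d <- .as_case(disease)
  s <- if (is.logical(stratum)) as.integer(stratum) else .as_case(stratum)
  if (length(unique(s)) < 2L) stop("stratum is constant")
  cells <- table(d, s)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty cell: disease=%s, stratum=%s",
                 rownames(cells)[bad[1]], colnames(cells)[bad[2]]))
  }
  df <- data.frame(x = values, d = d, s = s)
  if (!is.null(age)) df$age <- as.numeric(age)
  if (!is.null(sex)) df$sexM <- as.numeric(sex == "M")
  df <- df[complete.cases(df), , drop = FALSE]
  fit <- lm(x ~ . + d:s, data = df)
  sm <- summary(fit)$coefficients
  list(estimate = sm["d:s", "Estimate"], p = sm["d:s", "Pr(>|t|)"])
}

# JT statistic: ascending cross-group pairs, ties half-weighted.
.jt_stat <- function(groups) {
  k <- length(groups)
  s <- 0
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      s <- s + sum(outer(groups[[i]], groups[[j]], "<")) +
        0.5 * sum(outer(groups[[i]], groups[[j]], "=="))
    }
  }
  s
}

# All assignments of indices 1..N into ordered groups of the given sizes.
.jt_assignments <- function(n, sizes) {
  recurse <- function(avail, sizes) {
    if (length(sizes) == 1L) return(list(list(avail)))
    out <- list()
    picks <- combn(avail, sizes[1], simplify = FALSE)
    for (p in picks) {
      rest <- recurse(setdiff(avail, p), sizes[-1])
      for (r in rest) out[[length(out) + 1L]] <- c(list(p), r)
    }
    out
  }
  recurse(seq_len(n), sizes)
}

#' Jonckheere-Terpstra ordered trend test
#'
#' Tests for a monotone trend across ordered groups (e.g. healthy
#' controls then MMSE bands from best to worst). The statistic counts
#' ascending cross-group pairs with ties half-weighted. The p-value is
#' exact by exhaustive enumeration for total n <= 10 and a tie-corrected
#' normal approximation otherwise.
#'
#' @param groups list of numeric samples in the hypothesised order; at
#'   least 2 non-empty groups.
#' @param alternative `"two.sided"` (default), `"increasing"` or
#'   `"decreasing"`.
#' @return List with `JT`, `p`, and `method` (`"exact"` or `"normal"`).
#' @export
ordered_trend_test <- function(groups,
                               alternative = c("two.sided", "increasing",
                                               "decreasing")) {
  alternative <- match.arg(alternative)
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2L) stop("need at least 2 non-empty groups")
  sizes <- lengths(groups)
  n <- sum(sizes)
  obs <- .jt_stat(groups)
  pooled <- unlist(groups, use.names = FALSE)

  if (n <= 10L) {
    stats <- vapply(.jt_assignments(n, sizes), function(asg) {
      .jt_stat(lapply(asg, function(ix) pooled[ix]))
    }, numeric(1))
    p_up <- mean(stats >= obs - 1e-9)
    p_dn <- mean(stats <= obs + 1e-9)
    method <- "exact"
  } else {
    mu <- (n^2 - sum(sizes^2)) / 4
    t_sizes <- as.numeric(table(pooled))
    term1 <- (n * (n - 1) * (2 * n + 5) -
                sum(sizes * (sizes - 1) * (2 * sizes + 5)) -
                sum(t_sizes * (t_sizes - 1) * (2 * t_sizes + 5))) / 72
    term2 <- sum(sizes * (sizes - 1) * (sizes - 2)) *
      sum(t_sizes * (t_sizes - 1) * (t_sizes - 2)) /
      (36 * n * (n - 1) * (n - 2))
    term3 <- sum(sizes * (sizes - 1)) * sum(t_sizes * (t_sizes - 1)) /
      (8 * n * (n - 1))
    sigma <- sqrt(term1 + term2 + term3)
    p_up <- pnorm((obs - 0.5 - mu) / sigma, lower.tail = FALSE)
    p_dn <- pnorm((obs + 0.5 - mu) / sigma)
    method <- "normal"
  }
  p <- switch(alternative,
              increasing = p_up,
              decreasing = p_dn,
              two.sided = min(1, 2 * min(p_up, p_dn)))
  list(JT = obs, p = p, method = method)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Subjects missing either value are dropped pairwise; at least 4
#' complete pairs are required and constant input is an error.
#'
#' @param x,y numeric vectors.
#' @return List with `rho` and `p`.
#' @export
spearman_correlation <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input")
  ht <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p = ht$p.value)
}

#' Between-group deviation of pairwise correlations (Fisher z)
#'
#' For each listed variable pair, computes the Pearson correlation in the
#' reference (HC) and comparison (AD) groups and the Fisher z-difference
#' `z = (atanh r_hc - atanh r_ad) / sqrt(1/(n_hc-3) + 1/(n_ad-3))`, with
#' Benjamini-Hochberg adjustment across pairs.
#'
#' @param table_hc,table_ad [cohort_table()]s (or matrices) for the two
#'   groups; both must contain every listed variable.
#' @param pairs data.frame with columns `var1`, `var2`.
#' @return A data.frame `var1`, `var2`, `r_hc`, `r_ad`, `n_hc`, `n_ad`,
#'   `z`, `p`, `p_bh`.
#' @export
correlation_deviation <- function(table_hc, table_ad, pairs) {
  vh <- if (inherits(table_hc, "cohort_table")) table_hc$values else as.matrix(table_hc)
  va <- if (inherits(table_ad, "cohort_table")) table_ad$values else as.matrix(table_ad)
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    v1 <- pairs$var1[i]; v2 <- pairs$var2[i]
    okh <- complete.cases(vh[, v1], vh[, v2])
    oka <- complete.cases(va[, v1], va[, v2])
    nh <- sum(okh); na_ <- sum(oka)
    if (nh < 10L || na_ < 10L) {
      stop("need >= 10 complete subjects per group for pair ", v1, " / ", v2)
    }
    rh <- cor(vh[okh, v1], vh[okh, v2])
    ra <- cor(va[oka, v1], va[oka, v2])
    if (abs(rh) >= 1 || abs(ra) >= 1) {
      stop("|r| = 1 for pair ", v1, " / ", v2, "; Fisher z undefined")
    }
    z <- (atanh(rh) - atanh(ra)) / sqrt(1 / (nh - 3) + 1 / (na_ - 3))
    data.frame(var1 = v1, var2 = v2, r_hc = rh, r_ad = ra,
               n_hc = nh, n_ad = na_, z = z, p = 2 * pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$p_bh <- benjamini_hochberg(out$p)
  out
}

#' Stratified group comparison over a variable set
#'
#' Reusable wrapper for serology- or genotype-stratified reruns: applies
#' [mann_whitney_u()] per variable to case vs control values within the
#' subset selected by `filter_expr`, with BH adjustment across the
#' family. The filter expression is recorded in the output so the subset
#' is declarative.
#'
#' @param table a [cohort_table()].
#' @param meta aligned metadata.
#' @param variables variables forming the comparison family.
#' @param filter_expr a one-sided expression on `meta` columns as a
#'   string, e.g. `"ebv_pos"` or `"TRUE"` (everyone).
#' @return A data.frame `variable`, `subset`, `n_case`, `n_control`, `U`,
#'   `p`, `p_bh`.
#' @export
group_tests <- function(table, meta, variables = NULL, filter_expr = "TRUE") {
  stopifnot(identical(table$subject_ids, meta$subject_id))
  variables <- variables %||% table$variable_names
  keep <- eval(parse(text = filter_expr), envir = meta)
  keep <- rep_len(keep, nrow(meta)) & !is.na(keep)
  rows <- lapply(variables, function(v) {
    x <- table$values[keep & meta$group == "AD", v]
    y <- table$values[keep & meta$group == "HC", v]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    mw <- mann_whitney_u(x, y)
    data.frame(variable = v, subset = filter_expr,
               n_case = length(x), n_control = length(y),
               U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- benjamini_hochberg(out$p)
  out
}
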