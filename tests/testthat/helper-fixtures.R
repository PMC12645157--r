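# Shared fixture builders; everything is generated in code.

# A standardized cohort_table straight from a matrix of latent values.
std_table <- function(m, ids = sprintf("S%03d", seq_len(nrow(m))),
                      vars = sprintf("v%03d", seq_len(ncol(m)))) {
  dimnames(m) <- list(ids, vars)
  cohort_table(m, standardized = TRUE)
}

# Minimal valid metadata for n subjects (no spouses).
basic_meta <- function(ids, group, age = NULL, sex = NULL, seed = 1) {
  n <- length(ids)
  withr_seed <- function(expr) with_seed(seed, expr)
  data.frame(
    subject_id = ids, group = group,
    age = age %||% withr_seed(round(runif(n, 45, 83))),
    sex = sex %||% withr_seed(sample(c("M", "F"), n, TRUE)),
    stringsAsFactors = FALSE
  )
}

# Correlated multivariate data via a 5-factor model (for imputation tests).
factor_model_data <- function(n, p, seed) {
  with_seed(seed, {
    L <- matrix(rnorm(p * 5, sd = 0.6), p, 5)
    f <- matrix(rnorm(n * 5), n, 5)
    f %*% t(L) + matrix(rnorm(n * p, sd = 0.5), n, p)
  })
}

# Class-labelled Gaussian data with the first `n_inf` variables shifted by
# `d` in cases; returns list(table, labels).
planted_gaussian <- function(n1, n0, p, n_inf, d, seed) {
  with_seed(seed, {
    y <- rep(c(1, 0), c(n1, n0))
    m <- matrix(rnorm((n1 + n0) * p), n1 + n0, p)
    if (n_inf > 0) {
      m[y == 1, seq_len(n_inf)] <- m[y == 1, seq_len(n_inf)] + d
    }
    list(table = std_table(m), labels = y)
  })
}

# Brute-force AUC by explicit pair counting (independent oracle).
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (a in pos) for (b in neg) {
    s <- s + (a > b) + 0.5 * (a == b)
  }
  s / (length(pos) * length(neg))
}

# Grid-search Box-Cox profile log-likelihood (independent oracle).
boxcox_lambda_grid <- function(x, bounds = c(-5, 5), step = 0.01) {
  grid <- seq(bounds[1], bounds[2], by = step)
  ll <- vapply(grid, function(l) {
    y <- if (abs(l) < 1e-12) log(x) else (x^l - 1) / l
    -length(x) / 2 * log(mean((y - mean(y))^2)) + (l - 1) * sum(log(x))
  }, numeric(1))
  grid[which.max(ll)]
}
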