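test_that("missingness filter uses a strict > threshold at the boundary", {
  m <- matrix(runif(15, 1, 10), 5, 3,
              dimnames = list(paste0("S", 1:5), c("keep20", "drop40", "full")))
  m[1, "keep20"] <- NA              # 1/5 = 20% -> kept at threshold 0.20
  m[1:2, "drop40"] <- NA            # 2/5 = 40% -> dropped
  out <- filter_missingness(cohort_table(m), 0.20)
  expect_setequal(out$table$variable_names, c("keep20", "full"))
  expect_equal(out$dropped$variable, "drop40")
  expect_equal(out$dropped$missing_fraction, 0.4)
})

test_that("a complete table passes the filter unchanged with an empty report", {
  m <- matrix(runif(20, 1, 10), 5, 4,
              dimnames = list(paste0("S", 1:5), paste0("v", 1:4)))
  out <- filter_missingness(cohort_table(m), 0.20)
  expect_equal(out$table$values, m)
  expect_equal(nrow(out$dropped), 0L)
  expect_error(filter_missingness(cohort_table(m), 1.2), "threshold")
})

test_that("Box-Cox transform matches its closed forms at lambda 0, 1, 2", {
  x <- c(1, 2, 4)
  expect_equal(apply_boxcox(x, 0), log(x))
  expect_equal(apply_boxcox(x, 0), c(0, 0.6931, 1.3863), tolerance = 1e-4)
  expect_equal(apply_boxcox(x, 1), c(0, 1, 3))
  expect_equal(apply_boxcox(x, 2), c(0, 1.5, 7.5))
  expect_true(is.na(apply_boxcox(c(1, NA, 4), 1)[2]))
  expect_error(apply_boxcox(c(0, 1), 0.5, shift = 0), "non-positive")
})

test_that("fitted lambda matches the grid-search log-likelihood oracle", {
  x <- with_seed(31, exp(rnorm(5000)))
  lam <- fit_boxcox_lambda(x)
  expect_gt(lam, -0.15); expect_lt(lam, 0.15)
  expect_lt(abs(lam - boxcox_lambda_grid(x)), 0.011)

  g <- with_seed(32, rnorm(5000, 10, 1))
  lam_g <- fit_boxcox_lambda(g)
  expect_gt(lam_g, 0.5); expect_lt(lam_g, 2.0)
  expect_lt(abs(lam_g - boxcox_lambda_grid(g)), 0.011)
})

test_that("lambda estimates are clamped to the bounds and degenerate input handled", {
  x <- with_seed(33, exp(rnorm(500)))  # optimum near 0
  expect_equal(fit_boxcox_lambda(x, bounds = c(0.5, 0.9)), 0.5)
  expect_equal(fit_boxcox_lambda(x, bounds = c(-0.9, -0.5)), -0.5)
  expect_error(fit_boxcox_lambda(1:5), "at least 10")
  expect_warning(lam1 <- fit_boxcox_lambda(rep(2, 20)), "zero variance")
  expect_equal(lam1, 1)
})

test_that("shift convention guarantees strict positivity only when needed", {
  expect_equal(boxcox_shift(c(0, 1, 2)), 1)
  expect_equal(boxcox_shift(c(-2, 1)), 3)
  expect_equal(boxcox_shift(c(0.3, 5)), 0)
})

test_that("standardization matches hand computation and flags degenerate input", {
  z <- standardize(c(2, 4, 6))
  expect_equal(z$values, c(-1, 0, 1))
  expect_equal(z$sd, 2)
  r <- standardize(with_seed(1, runif(50)))$values
  expect_lt(abs(mean(r)), 1e-12)
  expect_equal(sd(r), 1)
  expect_error(standardize(c(5, 5, 5)), "zero variance")
  zz <- standardize(c(1, NA, 3))
  expect_true(is.na(zz$values[2]))
})

test_that("fit_transform yields mean 0 / SD 1 per variable and a reapplicable spec", {
  tr <- synthetic_truth(20, missingness_base_rate = 0.05, seed = 21)
  g <- generate_cohort(60, 40, tr)
  ft <- fit_transform(g$table)
  z <- ft$table$values
  expect_true(all(abs(colMeans(z, na.rm = TRUE)) < 1e-10))
  expect_true(all(abs(apply(z, 2, sd, na.rm = TRUE) - 1) < 1e-10))
  expect_true(all(ft$spec$lambda >= -5 & ft$spec$lambda <= 5))
  expect_true(all(ft$spec$sd > 0))
  # reapplication reproduces the transformed table
  z2 <- apply_transform(subset_cohort(g$table, variables = ft$spec$variable), ft$spec)
  expect_equal(z2$values, z)
  # spec JSON round trip
  p <- tempfile(fileext = ".json")
  write_transform_spec(ft$spec, p)
  expect_equal(as.data.frame(read_transform_spec(p)), as.data.frame(ft$spec),
               tolerance = 1e-12)
})

test_that("kNN imputation follows nearest-neighbour semantics on a worked example", {
  m <- matrix(c(1, 1, 10,
                1, 1, 10,
                NA, 5, 20), 3, 3,
              dimnames = list(c("A", "B", "C"), c("v1", "v2", "v3")))
  tab <- cohort_table(m)
  out <- knn_impute(tab, k = 1, check_scale = FALSE)
  expect_equal(out$values["A", "v3"], 5)       # B is A's nearest neighbour
  expect_equal(out$values[-1, ], m[-1, ])      # observed cells untouched
  expect_false(anyNA(out$values))
})

test_that("kNN falls back to the available donors with a warning", {
  m <- cbind(v1 = c(1, 1.1, 9), v2 = c(1, 1.2, 9.1), v3 = c(NA, 2, NA))
  rownames(m) <- c("A", "B", "C")
  # variable v3 observed only for subject B (value 2); both A and C warn
  w <- capture_warnings(out <- knn_impute(cohort_table(m), k = 3, check_scale = FALSE))
  expect_match(w, "donor", all = TRUE)
  expect_length(w, 2)
  expect_equal(out$values["A", "v3"], 2)
})

test_that("a complete table is returned unchanged and raw input is refused", {
  m <- matrix(rnorm(20), 5, 4,
              dimnames = list(paste0("S", 1:5), paste0("v", 1:4)))
  tab <- std_table(m)
  expect_identical(knn_impute(tab, 3), tab)
  raw <- matrix(runif(20, 50, 100), 5, 4,
                dimnames = list(paste0("S", 1:5), paste0("v", 1:4)))
  raw[1, 1] <- NA
  expect_error(knn_impute(cohort_table(raw), 3), "standardized")
})

test_that("monotone transforms preserve within-variable ranks of observed cells", {
  tr <- synthetic_truth(15, missingness_base_rate = 0.1, seed = 13)
  g <- generate_cohort(50, 40, tr)
  flt <- filter_missingness(g$table, 0.2)
  ft <- fit_transform(flt$table)
  for (v in ft$table$variable_names) {
    raw <- flt$table$values[, v]
    obs <- !is.na(raw)
    expect_equal(rank(ft$table$values[obs, v]), rank(raw[obs]))
  }
})

test_that("kNN beats mean imputation on correlated MAR data", {
  wins <- 0L
  for (s in 1:5) {
    x <- factor_model_data(200, 50, seed = 100 + s)
    x <- scale(x)
    truth_vals <- x
    mask <- with_seed(200 + s, matrix(runif(length(x)) < 0.10, nrow(x), ncol(x)))
    x[mask] <- NA
    tab <- std_table(x)
    imp <- knn_impute(tab, k = 3)
    rmse_knn <- sqrt(mean((imp$values[mask] - truth_vals[mask])^2))
    mean_fill <- x
    for (j in seq_len(ncol(x))) {
      mean_fill[is.na(x[, j]), j] <- mean(x[, j], na.rm = TRUE)
    }
    rmse_mean <- sqrt(mean((mean_fill[mask] - truth_vals[mask])^2))
    wins <- wins + (rmse_knn < rmse_mean)
  }
  expect_gte(wins, 4L)
})
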