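test_that("AUC matches trivial cases and handles ties as one half", {
  expect_equal(auc_roc(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_roc(c(0.9, 0.3, 0.8, 0.4), c(1, 1, 0, 0)), 0.5)
  expect_equal(auc_roc(rep(0.7, 10), rep(c(1, 0), 5)), 0.5)
  expect_error(auc_roc(1:4, rep(1, 4)), "both classes")
})

test_that("AUC agrees exactly with brute-force pair counting on random instances", {
  for (s in 1:100) {
    dat <- with_seed(1500 + s, {
      n <- sample(10:50, 1)
      y <- c(1, 0, rbinom(n - 2, 1, 0.5))
      sc <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
      list(y = y, sc = sc)
    })
    expect_identical(auc_roc(dat$sc, dat$y), auc_brute(dat$sc, dat$y))
  }
})

test_that("stratified folds balance classes, partition subjects, and are seed-deterministic", {
  y <- rep(c(1, 0), c(20, 10))
  f <- stratified_kfold(y, 10, seed = 4)
  tab <- table(f, y)
  expect_true(all(tab[, "1"] == 2))
  expect_true(all(tab[, "0"] == 1))
  expect_identical(f, stratified_kfold(y, 10, seed = 4))
  expect_false(identical(f, stratified_kfold(y, 10, seed = 5)))
  expect_setequal(unique(f), 1:10)
  expect_length(f, 30)
  expect_error(stratified_kfold(rep(c(1, 0), c(5, 20)), 10, seed = 1),
               "fewer members")
})

test_that("optimal N is the smallest argmax of the mean AUC curve", {
  mk <- function(m) structure(list(curve = data.frame(n_features = seq_along(m),
                                                      mean_auc = m)),
                              class = "cv_curve")
  expect_equal(select_optimal_n(mk(c(0.6, 0.7, 0.7, 0.65))), 2)
  expect_equal(select_optimal_n(mk(c(0.5, 0.6, 0.7))), 3)
  expect_equal(select_optimal_n(mk(0.8)), 1)
})

test_that("a strongly separating variable yields near-perfect CV AUC at N = 1", {
  pg <- planted_gaussian(100, 100, 6, n_inf = 1, d = 3, seed = 8)
  cv <- incremental_l2_curve(pg$table, pg$labels,
                             ranking = pg$table$variable_names,
                             max_features = 3, k = 5, seed = 2)
  expect_gt(cv$curve$mean_auc[1], 0.95)
  expect_true(all(cv$fold_auc >= 0 & cv$fold_auc <= 1))
  expect_true(all(cv$curve$ci_low <= cv$curve$mean_auc &
                    cv$curve$mean_auc <= cv$curve$ci_high))
})

test_that("held-out AUC collapses to chance under the null (no leakage)", {
  pg <- planted_gaussian(200, 200, 20, n_inf = 0, d = 0, seed = 17)
  cv <- incremental_l2_curve(pg$table, pg$labels,
                             ranking = pg$table$variable_names,
                             max_features = 10, k = 10, seed = 3)
  expect_true(all(abs(cv$curve$mean_auc - 0.5) < 0.06))
})

test_that("ranking truncation and unknown variables are handled", {
  pg <- planted_gaussian(30, 30, 4, 0, 0, seed = 5)
  expect_warning(cv <- incremental_l2_curve(pg$table, pg$labels,
                                            ranking = pg$table$variable_names,
                                            max_features = 10, k = 3, seed = 1),
                 "truncating")
  expect_equal(nrow(cv$curve), 4)
  expect_error(incremental_l2_curve(pg$table, pg$labels, ranking = "nope",
                                    max_features = 1, k = 3, seed = 1),
               "unknown variables")
})

test_that("averaged ROC matches vertical-averaging expectations", {
  # identical folds -> zero-width band
  sc <- c(0.9, 0.8, 0.3, 0.2); lb <- c(1, 1, 0, 0)
  r <- averaged_roc(list(sc, sc), list(lb, lb))
  expect_true(all(r$ci_high - r$ci_low < 1e-12))
  # perfect folds pass through (0, 1)
  expect_equal(r$tpr[r$fpr == 0], 1)
  expect_equal(attr(r, "auc"), 1, tolerance = 1e-9)

  # one perfect fold + one chance-level fold -> AUC about 0.75
  perfect <- list(s = c(10, 9, 8, 1, 0.5, 0.2), l = c(1, 1, 1, 0, 0, 0))
  flat <- with_seed(23, list(s = rnorm(200), l = rbinom(200, 1, 0.5)))
  r2 <- averaged_roc(list(perfect$s, flat$s), list(perfect$l, flat$l))
  expect_gt(attr(r2, "auc"), 0.70)
  expect_lt(attr(r2, "auc"), 0.80)

  # single-class fold is skipped with a warning
  expect_warning(
    r3 <- averaged_roc(list(sc, sc, c(1, 2)), list(lb, lb, c(1, 1))),
    "single class")
  expect_error(averaged_roc(list(sc), list(lb)), ">= 2")
})

test_that("ridge curve with covariates keeps age and sex unpenalised", {
  # outcome driven by age only: the covariate-adjusted model must exploit it
  dat <- with_seed(29, {
    n <- 300
    age <- round(runif(n, 45, 83))
    pr <- stats::plogis(0.08 * (age - 64))
    y <- rbinom(n, 1, pr)
    x <- matrix(rnorm(n * 3), n, 3)
    list(age = age, y = y, x = x)
  })
  tab <- std_table(dat$x)
  cv <- incremental_l2_curve(tab, dat$y, tab$variable_names,
                             age = dat$age, sex = NULL,
                             max_features = 3, k = 5, seed = 11)
  expect_gt(cv$curve$mean_auc[1], 0.6)
})
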