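test_that("Mann-Whitney U matches the exact enumeration case", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)  # 2/20 arrangements as extreme, two-sided
  # swapping groups reflects U and keeps p
  res2 <- mann_whitney_u(c(4, 5, 6), c(1, 2, 3))
  expect_equal(res2$U, 9)   # n1*n2 - U
  expect_equal(res2$p, res$p)
  # identical samples give no evidence
  x <- c(1.2, 3.4, 2.2, 5.1)
  expect_gt(mann_whitney_u(x, x)$p, 0.9)
  expect_error(mann_whitney_u(numeric(), 1:3), "non-empty")
})

test_that("Benjamini-Hochberg matches the hand-computed step-up example", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  p <- with_seed(81, runif(50))
  expect_true(all(benjamini_hochberg(p) >= p))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Kruskal-Wallis H matches the rank-sum hand computation", {
  res <- kruskal_wallis_pairwise(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(res$H, 4.5714, tolerance = 1e-3)
  expect_true(all(res$pairwise >= 0 & res$pairwise <= 1))
  expect_identical(res$pairwise, t(res$pairwise))
  expect_equal(unname(diag(res$pairwise)), rep(1, 3))

  same <- with_seed(82, rnorm(15))
  res0 <- kruskal_wallis_pairwise(list(same, same, same))
  expect_lt(res0$H, 1e-9)
  expect_gt(res0$p, 0.99)
  expect_error(kruskal_wallis_pairwise(list(1:3, 4:6)), ">= 3 groups")
})

test_that("interaction test controls type-I error and detects planted interactions", {
  rej_null <- 0L
  for (s in 1:50) {
    dat <- with_seed(1100 + s, {
      d <- rbinom(400, 1, 0.5); st <- rbinom(400, 1, 0.5)
      x <- 0.5 * d + 0.4 * st + rnorm(400)
      list(x = x, d = d, st = st)
    })
    rej_null <- rej_null + (interaction_test(dat$x, dat$d, dat$st)$p < 0.05)
  }
  expect_lte(rej_null, 8L)   # ~alpha * 50 with binomial slack

  rej_alt <- 0L
  for (s in 1:10) {
    dat <- with_seed(1200 + s, {
      d <- rbinom(400, 1, 0.5); st <- rbinom(400, 1, 0.5)
      x <- 0.5 * d + 0.4 * st + 0.8 * d * st + rnorm(400)
      list(x = x, d = d, st = st)
    })
    rej_alt <- rej_alt + (interaction_test(dat$x, dat$d, dat$st)$p < 0.05)
  }
  expect_gte(rej_alt, 8L)

  expect_error(interaction_test(rnorm(20), rep(c(1, 0), 10), rep(1, 20)),
               "constant")
  expect_error(interaction_test(rnorm(4), c(1, 1, 0, 0), c(1, 1, 0, 0)),
               "empty cell")
})

test_that("Jonckheere-Terpstra exact p matches exhaustive enumeration", {
  res <- ordered_trend_test(list(c(1, 2), c(3, 4), c(5, 6)),
                            alternative = "increasing")
  expect_equal(res$JT, 12)
  expect_equal(res$p, 1 / 90)
  expect_equal(res$method, "exact")
  # reversing the group order flips the one-sided tail
  rev_res <- ordered_trend_test(list(c(5, 6), c(3, 4), c(1, 2)),
                                alternative = "decreasing")
  expect_equal(rev_res$p, 1 / 90)
  expect_error(ordered_trend_test(list(1:3)), "at least 2")
})

test_that("Jonckheere-Terpstra normal approximation is calibrated under the null", {
  rej <- 0L
  for (s in 1:100) {
    groups <- with_seed(1300 + s, list(rnorm(15), rnorm(15), rnorm(15)))
    rej <- rej + (ordered_trend_test(groups)$p < 0.05)
  }
  expect_gte(rej, 1L); expect_lte(rej, 12L)
  # monotone shift is detected
  shifted <- with_seed(1301, list(rnorm(15), rnorm(15) + 1, rnorm(15) + 2))
  expect_lt(ordered_trend_test(shifted, "increasing")$p, 0.001)
})

test_that("Spearman correlation matches hand rank computations", {
  expect_equal(spearman_correlation(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_correlation(1:8, -(1:8))$rho, -1)
  res <- spearman_correlation(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(res$rho, 1 - 6 * 4 / (5 * 24))   # sum d^2 = 4 -> rho 0.8
  expect_equal(res$rho, cor(1:5, c(2, 1, 4, 3, 5), method = "spearman"))
  expect_error(spearman_correlation(1:3, 1:3), "at least 4")
  expect_error(spearman_correlation(1:10, rep(2, 10)), "constant")
  # pairwise-complete handling
  res2 <- spearman_correlation(c(1:6, NA), c(2, 1, 4, 3, 6, 5, 10))
  expect_equal(res2$rho, cor(1:6, c(2, 1, 4, 3, 6, 5), method = "spearman"))
})

test_that("correlation deviation matches the Fisher z closed form", {
  # exact sample correlations 0.9 (HC) and 0.0 (AD) at n = 100 each
  mk <- function(r, seed) {
    q <- with_seed(seed, qr.Q(qr(cbind(1, matrix(rnorm(200), 100, 2)))))[, -1]
    q <- sweep(q, 2, apply(q, 2, sd), "/")
    cbind(v1 = q[, 1], v2 = r * q[, 1] + sqrt(1 - r^2) * q[, 2])
  }
  tab_hc <- mk(0.9, 91); tab_ad <- mk(0.0, 92)
  res <- correlation_deviation(tab_hc, tab_ad,
                               data.frame(var1 = "v1", var2 = "v2"))
  expect_equal(res$z, atanh(0.9) / sqrt(2 / 97), tolerance = 1e-6)
  expect_equal(res$z, 10.25, tolerance = 0.01)
  expect_lt(res$p, 1e-20)
  # swapping groups negates z with the same p
  res_sw <- correlation_deviation(tab_ad, tab_hc,
                                  data.frame(var1 = "v1", var2 = "v2"))
  expect_equal(res_sw$z, -res$z)
  expect_equal(res_sw$p, res$p)
  # equal correlations give z = 0, p = 1
  res_eq <- correlation_deviation(tab_hc, tab_hc,
                                  data.frame(var1 = "v1", var2 = "v2"))
  expect_equal(res_eq$z, 0)
  expect_equal(res_eq$p, 1)
  expect_error(correlation_deviation(cbind(v1 = 1:20, v2 = 1:20),
                                     tab_ad, data.frame(var1 = "v1", var2 = "v2")),
               "Fisher z undefined")
})

test_that("stratified group tests record the subset and adjust within the family", {
  tr <- synthetic_truth(10, missingness_base_rate = 0, seed = 83)
  g <- generate_cohort(60, 60, tr)
  z <- fit_transform(g$table)$table
  res <- group_tests(z, g$meta, filter_expr = "ebv_pos")
  expect_equal(unique(res$subset), "ebv_pos")
  expect_equal(nrow(res), 10)
  expect_true(all(res$p_bh >= res$p))
  expect_true(all(res$n_case <= 60 & res$n_control <= 60))
})
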