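# Small cohort with planted spousal structure for re-pairing tests.
spousal_cohort <- function(n_pairs, n_vars, rho, seed, extra_hc = 0) {
  tr <- synthetic_truth(n_vars,
                        shared_env_variables = if (rho > 0) synth_var_names(n_vars) else character(),
                        shared_env_rho = rho,
                        missingness_base_rate = 0, seed = seed)
  g <- generate_cohort(n_pairs, n_pairs + extra_hc, tr, n_pairs = n_pairs)
  g$z <- fit_transform(g$table)$table
  g
}

test_that("pair distances follow the Euclidean closed form", {
  m <- rbind(A = c(1, 2), B = c(4, 6), C = c(1, 2))
  colnames(m) <- c("v1", "v2")
  tab <- std_table(m, ids = rownames(m), vars = colnames(m))
  pr <- structure(list(pairs = data.frame(a = c("A", "C"), b = c("B", "A")),
                       kind = "actual"), class = "pairing_set")
  d <- pair_distances(tab, pr)
  expect_equal(unname(d), c(5, 0))
  # subset monotonicity
  d1 <- pair_distances(tab, pr, "v1")
  expect_true(all(d1 <= d + 1e-12))
  expect_error(pair_distances(tab, structure(list(pairs = data.frame(a = "A", b = "Z")),
                                             class = "pairing_set")),
               "missing from table")
})

test_that("simulated pairings preserve sex composition and are seed-deterministic", {
  g <- spousal_cohort(30, 5, rho = 0, seed = 71)
  act <- actual_pairings(g$meta)
  expect_equal(nrow(act$pairs), 30)
  sims <- simulate_pairings(g$meta, act, n_sets = 20, seed = 5)
  sims2 <- simulate_pairings(g$meta, act, n_sets = 20, seed = 5)
  expect_identical(lapply(sims, `[[`, "pairs"), lapply(sims2, `[[`, "pairs"))

  sex_of <- function(ids) g$meta$sex[match(ids, g$meta$subject_id)]
  actual_comp <- sort(paste0(sex_of(act$pairs$a), sex_of(act$pairs$b)))
  for (s in sims) {
    expect_identical(sort(paste0(sex_of(s$pairs$a), sex_of(s$pairs$b))),
                     actual_comp)
    expect_equal(anyDuplicated(c(s$pairs$a, s$pairs$b)), 0L)
    expect_true(is.numeric(s$n_unchanged))
  }
  # different seeds give different re-pairings
  expect_false(identical(sims[[1]]$pairs, sims[[2]]$pairs))
})

test_that("simulated within-pair age gaps track the actual gap distribution", {
  g <- spousal_cohort(39, 5, rho = 0, seed = 72)
  act <- actual_pairings(g$meta)
  age_of <- function(ids) g$meta$age[match(ids, g$meta$subject_id)]
  gaps_act <- age_of(act$pairs$a) - age_of(act$pairs$b)
  ok <- 0L
  for (s in 1:10) {
    sim <- simulate_pairings(g$meta, act, 1, age_bin_width = 10, seed = 100 + s)[[1]]
    gaps_sim <- age_of(sim$pairs$a) - age_of(sim$pairs$b)
    p <- suppressWarnings(stats::ks.test(gaps_act, gaps_sim)$p.value)
    ok <- ok + (p > 0.05)
  }
  expect_gte(ok, 7L)
})

test_that("distance comparison returns no signal when actual equals the simulated sets", {
  d <- with_seed(73, runif(20, 1, 5))
  res <- compare_distance_distributions(d, replicate(50, d, simplify = FALSE))
  expect_equal(res$p_perm, 1)
  expect_gt(res$p_mw, 0.9)
  expect_error(compare_distance_distributions(numeric(), list(d)), "non-empty")
})

test_that("shared environment shrinks actual distances relative to simulated pairings", {
  g <- spousal_cohort(100, 30, rho = 0.6, seed = 74)
  act <- actual_pairings(g$meta)
  sims <- simulate_pairings(g$meta, act, 99, seed = 7)
  d_act <- pair_distances(g$z, act)
  d_sim <- lapply(sims, function(s) pair_distances(g$z, s))
  res <- compare_distance_distributions(d_act, d_sim)
  expect_lt(res$median_actual, res$median_simulated)
  expect_lt(res$p_perm, 0.05)
  expect_lt(res$p_mw, 0.01)
})

test_that("concordance scatter flags planted shared-environment variables", {
  vn <- synth_var_names(30)
  tr <- synthetic_truth(30, shared_env_variables = vn[1:10], shared_env_rho = 0.6,
                        missingness_base_rate = 0, seed = 75)
  g <- generate_cohort(150, 150, tr, n_pairs = 150)
  z <- fit_transform(g$table)$table
  act <- actual_pairings(g$meta)
  sims <- simulate_pairings(g$meta, act, 60, seed = 11)
  sc <- concordance_pvalue_scatter(z, act, sims, flag_variables = vn[1:10],
                                   seed = 3)
  tab <- sc$table
  planted <- tab[tab$variable %in% vn[1:10], ]
  expect_gte(mean(planted$p_actual < planted$p_simulated), 0.8)
  expect_true(all(c("p_actual", "p_simulated", "flagged") %in% names(tab)))
  expect_equal(sum(tab$flagged), 10)
})

test_that("degenerate concordance inputs are handled", {
  g <- spousal_cohort(10, 4, rho = 0, seed = 76)
  act <- actual_pairings(g$meta)
  sims <- simulate_pairings(g$meta, act, 5, seed = 2)
  m <- g$z$values
  m[, 1] <- 0
  tab0 <- std_table(m, ids = rownames(m), vars = colnames(m))
  expect_warning(sc <- concordance_pvalue_scatter(tab0, act, sims, seed = 1),
                 "constant variable")
  expect_false(colnames(m)[1] %in% sc$table$variable)
})
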