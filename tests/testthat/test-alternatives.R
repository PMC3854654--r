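# The four comparison approaches, exercised on small planted scenarios.

test_that("A1 standardizes to max 1 and rejects all-zero input", {
  set.seed(22)
  cohorts <- generate_cohorts(small_scenario())
  d0 <- initial_dissimilarity(cohorts)
  tr <- approach_a1(d0)
  expect_s3_class(tr, "eaccd_tree")
  expect_equal(max(cophenetic_matrix(tr)) <= 1 + 1e-12, TRUE)

  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_error(approach_a1(z), "no separation")
})

test_that("A2 dissimilarities are 1 - p and bounded in [0,1]", {
  set.seed(23)
  cohorts <- generate_cohorts(small_scenario())
  res <- approach_a2(cohorts)
  expect_true(all(res$dis >= 0 & res$dis <= 1))
  p <- weighted_two_sample_test(cohorts[[1]], cohorts[[2]], "logrank")$p_value
  expect_equal(res$dis[1, 2], 1 - p)

  # two identical cohorts: p = 1, dissimilarity 0
  ch <- combination_cohort("A", c(F = "1"), c(1, 2, 3), c(1, 1, 0))
  ch2 <- ch; ch2$label <- "B"
  expect_equal(approach_a2(list(ch, ch2))$dis["A", "B"], 0)
})

test_that("A3 ignores survival: identical covariates -> distance 0", {
  cohorts <- generate_cohorts(identical_covariate_scenario())
  res <- approach_a3(cohorts)
  # T1N0 and T1N1 have identical covariates but hazards 0.005 vs 0.05
  expect_equal(res$dis["T1N0", "T1N1"], 0)
  expect_gt(initial_dissimilarity(cohorts)["T1N0", "T1N1"], 50)
  expect_equal(max(res$dis), 1)
  expect_true(all(res$summaries$t_hat_s >= 0 & res$summaries$t_hat_s <= 1))
  expect_equal(range(res$summaries$n_hat_s), c(0, 1))
})

test_that("A3 output never reads survival times", {
  cohorts <- generate_cohorts(identical_covariate_scenario())
  scrambled <- lapply(cohorts, function(ch) {
    ch$time <- rev(ch$time) * 7 + 1   # monotone relabeling + reshuffle
    ch
  })
  expect_equal(approach_a3(cohorts)$dis, approach_a3(scrambled)$dis)
})

test_that("A3 requires raw covariates and a nonzero spread", {
  ch <- combination_cohort("A", c(F = "1"), c(1, 2), c(1, 1))
  expect_error(approach_a3(list(ch, ch)), "lacks raw covariates")
})

test_that("A3* consensus keeps identical-covariate pairs together at any m", {
  # K capped at 4: with six combinations containing two zero-distance pairs,
  # K = 5 would force one such pair apart by pigeonhole
  cohorts <- generate_cohorts(identical_covariate_scenario())
  for (m in c(1, 50)) {
    res <- approach_a3_star(cohorts, ensemble_config(m = m, k_max = 4, seed = 44))
    expect_equal(res$dis["T1N0", "T1N1"], 0)
    expect_true(all(res$dis >= 0 & res$dis <= 1))
  }
})

test_that("A3 disagrees with survival-based clustering when groups cut across the grid", {
  cohorts <- generate_cohorts(identical_covariate_scenario())
  fit <- run_eaccd(cohorts, config = ensemble_config(m = 500, k_max = 5, seed = 5))
  a3 <- approach_a3(cohorts)
  # survival puts T1N0 and T1N1 far apart; covariates put them at distance 0
  expect_lt(adjusted_rand(cut_tree(a3$tree, 3), cut_tree(fit$tree, 3)), 1)
})

test_that("A3 agrees with survival clustering when groups align with the grid", {
  # Positive control: outcome groups = T level on a 2 x 2 grid.  The two
  # tumor means standardize to exactly 0 and 1, so the between-group L1
  # distance is at least 1, while within-group distance is pure node-mean
  # sampling noise (at most 1 after min-max stretching, and tiny before it);
  # the k = 2 cut of both trees must recover the T split.
  sc <- scenario_spec(
    factor_levels = list(T = 1:2, N = 0:1),
    group_of = c(T1N0 = 1, T1N1 = 1, T2N0 = 2, T2N1 = 2),
    hazard_of = c(0.005, 0.08),
    n_of = 600,
    covariate_ranges = list(
      tumor_size_cm = list(factor = "T", integer = FALSE,
                           ranges = list(`1` = c(0.5, 1.5), `2` = c(8, 12))),
      node_count = list(factor = "N", integer = TRUE,
                        ranges = list(`0` = c(1, 3), `1` = c(1, 3)))),
    seed = 55)
  cohorts <- generate_cohorts(sc)
  truth <- c(T1N0 = 1, T1N1 = 1, T2N0 = 2, T2N1 = 2)[names(cohorts)]
  fit <- run_eaccd(cohorts, config = ensemble_config(m = 800, k_max = 3, seed = 6))
  a3 <- approach_a3(cohorts)
  expect_equal(adjusted_rand(cut_tree(fit$tree, 2), truth), 1)
  expect_equal(adjusted_rand(cut_tree(a3$tree, 2), truth), 1)
})

test_that("A4 returns one locally optimal partition per requested k", {
  set.seed(24)
  cohorts <- generate_cohorts(small_scenario())
  d0 <- initial_dissimilarity(cohorts)
  parts <- approach_a4(d0, k_list = c(1, 2, 4))
  expect_named(parts, c("k1", "k2", "k4"))
  expect_equal(parts$k1$medoids, unname(which.min(rowSums(d0))))
  expect_equal(parts$k4$objective, 0)
  # k = 2 recovers the planted blocks here
  expect_equal(adjusted_rand(parts$k2$assignment, c(1, 1, 2, 2)), 1)
})
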