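test_that("initial dissimilarity is a valid symmetric matrix of statistics", {
  set.seed(21)
  cohorts <- generate_cohorts(small_scenario())
  d0 <- initial_dissimilarity(cohorts, "logrank")
  expect_equal(dim(d0), c(4, 4))
  expect_equal(rownames(d0), names(cohorts))
  expect_equal(d0, t(d0))
  expect_equal(diag(d0), setNames(rep(0, 4), rownames(d0)))
  # same planted group -> small statistic; different groups -> large
  expect_lt(d0["T1N0", "T1N1"], min(d0["T1N0", "T2N0"], d0["T1N0", "T2N1"]))
  # entries are exactly the pairwise test statistics
  expect_equal(d0["T1N0", "T2N1"],
               weighted_two_sample_test(cohorts$T1N0, cohorts$T2N1,
                                        "logrank")$statistic)
})

test_that("identical cohorts get zero dissimilarity; degenerate pairs warn", {
  ch <- combination_cohort("A", c(F = "1"), c(1, 2, 3), c(1, 1, 0))
  ch2 <- ch; ch2$label <- "B"
  d0 <- initial_dissimilarity(list(ch, ch2))
  expect_equal(d0["A", "B"], 0)

  cens <- combination_cohort("C", c(F = "1"), c(1, 2), c(0, 0))
  cens2 <- cens; cens2$label <- "D"
  expect_warning(d0 <- initial_dissimilarity(list(cens, cens2)), "degenerate")
  expect_equal(d0["C", "D"], 0)
})

test_that("pam_partition handles the degenerate k cases", {
  set.seed(3)
  d <- random_dissimilarity(7)
  p1 <- pam_partition(d, 1)
  expect_equal(p1$medoids, unname(which.min(rowSums(d))))
  expect_equal(p1$objective, min(rowSums(d)))

  pn <- pam_partition(d, 7)
  expect_equal(pn$objective, 0)
  expect_equal(sort(pn$medoids), 1:7)
  expect_error(pam_partition(d, 8), "k must be")
})

test_that("pam partitions satisfy their structural invariants", {
  set.seed(31)
  for (i in 1:20) {
    d <- random_dissimilarity(sample(5:9, 1))
    k <- sample(2:4, 1)
    p <- pam_partition(d, k, init = sample(c("random", "build"), 1))
    expect_setequal(unique(p$assignment), 1:k)
    # each medoid belongs to its own cluster
    expect_equal(unname(p$assignment[p$medoids]), seq_len(k))
    # objective equals recomputed within-cluster scatter to medoids
    expect_equal(p$objective,
                 sum(d[cbind(seq_len(nrow(d)), p$medoids[p$assignment])]),
                 tolerance = 1e-12)
    # swap phase strictly decreases the objective at every accepted swap
    expect_true(all(diff(p$objective_trace) < 0) || length(p$objective_trace) == 1)
  }
})

test_that("pam never beats the exhaustive optimum and usually attains it", {
  set.seed(41)
  hits <- 0
  n_cases <- 60
  for (i in seq_len(n_cases)) {
    d <- random_dissimilarity(7)
    k <- sample(2:3, 1)
    opt <- oracle_pam_optimum(d, k)
    single <- pam_partition(d, k, init = "random")$objective
    expect_gte(single, opt - 1e-9)
    best20 <- min(replicate(20, pam_partition(d, k, init = "random")$objective))
    if (abs(best20 - opt) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits / n_cases, 0.95)
})

test_that("pam agrees with cluster::pam on build initialisation", {
  set.seed(51)
  for (i in 1:10) {
    d <- random_dissimilarity(8)
    k <- sample(2:4, 1)
    ours <- pam_partition(d, k, init = "build")
    ref <- cluster::pam(stats::as.dist(d), k, do.swap = TRUE)
    # compare the achieved objective (average form used by cluster::pam)
    expect_equal(ours$objective / nrow(d), unname(ref$objective["swap"]),
                 tolerance = 1e-8)
  }
})

test_that("ensemble dissimilarity obeys its contract", {
  set.seed(61)
  cohorts <- generate_cohorts(small_scenario())
  d0 <- initial_dissimilarity(cohorts)

  # m = 1: entries are a single 0/1 indicator
  c1 <- ensemble_dissimilarity(d0, ensemble_config(m = 1, k_max = 3, seed = 1))
  expect_true(all(c1 %in% c(0, 1)))
  expect_equal(diag(c1), setNames(rep(0, 4), rownames(d0)))

  cm <- ensemble_dissimilarity(d0, ensemble_config(m = 500, k_max = 3, seed = 2))
  expect_true(all(cm >= 0 & cm <= 1))
  expect_equal(cm, t(cm))

  # reproducibility: identical seed => bit-identical matrix
  cm2 <- ensemble_dissimilarity(d0, ensemble_config(m = 500, k_max = 3, seed = 2))
  expect_identical(cm, cm2)

  expect_error(ensemble_dissimilarity(d0, ensemble_config(m = 10, k_min = 2, k_max = 4)),
               "invalid K range")
  expect_error(ensemble_config(m = 0), "m must be")
})

test_that("ensemble separates planted blocks", {
  # two blocks of 4 with between-block dissimilarity far above within
  d <- matrix(5, 8, 8) + matrix(runif(64, 0, 0.1), 8, 8)
  d[1:4, 1:4] <- 0.2
  d[5:8, 5:8] <- 0.2
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(paste0("x", 1:8), paste0("x", 1:8))
  cm <- ensemble_dissimilarity(d, ensemble_config(m = 2000, k_min = 2, k_max = 4,
                                                  seed = 9))
  within <- c(cm[1:4, 1:4][upper.tri(diag(4))], cm[5:8, 5:8][upper.tri(diag(4))])
  between <- cm[1:4, 5:8]
  expect_lt(max(within), 0.5)
  expect_gt(min(between), 0.5)
  expect_gt(min(between), 0.95)  # blocks separated in nearly every run
})

test_that("a custom partitioner collection is honoured", {
  d <- random_dissimilarity(5)
  # a partitioner that always isolates point 1
  iso1 <- function(dis, k) c(2L, rep(1L, nrow(dis) - 1))
  cm <- ensemble_dissimilarity(d, ensemble_config(m = 50, k_max = 4,
                                                  partitioners = list(iso1),
                                                  seed = 3))
  expect_true(all(cm[1, -1] == 1))
  expect_true(all(cm[-1, -1] == 0))
})

test_that("agglomerate reproduces stats::hclust on tie-free matrices", {
  set.seed(71)
  for (i in 1:30) {
    n <- sample(5:7, 1)
    d <- random_dissimilarity(n)
    for (lk in c("average", "complete", "single")) {
      ours <- agglomerate(d, lk)
      ref <- stats::hclust(stats::as.dist(d), method = lk)
      expect_equal(sort(ours$height), sort(ref$height), tolerance = 1e-12)
      expect_equal(tree_clades(ours), clades_of(ref$merge, ref$labels))
    }
  }
})

test_that("two-point tree and ultrametric fixed point", {
  d <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr <- agglomerate(d, "single")
  expect_equal(tr$height, 0.4)
  expect_error(agglomerate(d[1, 1, drop = FALSE]), "labels|at least")

  # cophenetic matrix of any tree is an ultrametric fixed point of agglomerate
  set.seed(81)
  u <- cophenetic_matrix(agglomerate(random_dissimilarity(6), "average"))
  for (lk in c("average", "complete", "single"))
    expect_equal(cophenetic_matrix(agglomerate(u, lk)), u, tolerance = 1e-12)
})

test_that("cophenetic matrices satisfy the three-point ultrametric condition", {
  set.seed(91)
  cm <- cophenetic_matrix(agglomerate(random_dissimilarity(6), "complete"))
  n <- nrow(cm)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n)
    expect_lte(cm[i, j], max(cm[i, k], cm[j, k]) + 1e-12)
})

test_that("cut_tree returns the k clusters present after undoing merges", {
  set.seed(14)
  d <- random_dissimilarity(6)
  tr <- agglomerate(d, "average")
  expect_equal(unname(cut_tree(tr, 1)), rep(1, 6))
  expect_equal(length(unique(cut_tree(tr, 6))), 6)
  expect_error(cut_tree(tr, 7), "k must be")
  # cutting at k and k+1 nests
  c3 <- cut_tree(tr, 3); c4 <- cut_tree(tr, 4)
  expect_true(all(tapply(c3, c4, function(x) length(unique(x))) == 1))
})

test_that("merge heights are non-decreasing and ties break lexicographically", {
  set.seed(15)
  for (lk in c("average", "complete", "single")) {
    tr <- agglomerate(random_dissimilarity(7), lk)
    expect_true(all(diff(tr$height) >= -1e-12))
  }
  # all-equal matrix: first merge must unite the two lowest-labelled leaves
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  tr <- agglomerate(d, "average")
  expect_equal(sort(tr$merge[1, ]), c(-2L, -1L))
})

test_that("the full pipeline composes and is reproducible from the seed", {
  cohorts <- generate_cohorts(small_scenario())
  cfg <- ensemble_config(m = 300, k_max = 3, seed = 17)
  fit1 <- run_eaccd(cohorts, "logrank", cfg, "average")
  fit2 <- run_eaccd(cohorts, "logrank", cfg, "average")
  expect_identical(fit1$dis, fit2$dis)
  expect_identical(fit1$tree$merge, fit2$tree$merge)
  expect_identical(fit1$tree$height, fit2$tree$height)
  expect_true(all(fit1$dis >= 0 & fit1$dis <= 1))
  # planted two-group structure is recovered at the k = 2 cut
  expect_equal(adjusted_rand(cut_tree(fit1$tree, 2), c(1, 1, 2, 2)), 1)
})
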