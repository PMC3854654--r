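# Four simpler clustering approaches used as comparators for the ensemble
# pipeline.  A1, A2 and A4 work from the survival-test dissimilarity without
# the learning step; A3 ignores survival entirely and clusters on the raw
# covariate means; A3* reinstates the learning step on top of A3's distance.

#' Approach A1: standardized initial dissimilarity, no learning step
#'
#' Divides the initial dissimilarity by its global maximum (so the largest
#' entry is exactly 1) and applies average-linkage agglomeration directly.
#' Because the test statistic grows with the number of patients compared,
#' this approach is sensitive to the relative sizes of the combinations: a
#' much larger combination inflates its dissimilarities and tends to end up
#' as a root-adjacent singleton.
#'
#' @param dis0 initial dissimilarity matrix with a strictly positive maximum.
#' @return an `eaccd_tree` (average linkage).
#' @export
approach_a1 <- function(dis0) {
  validate_dissimilarity(dis0)
  mx <- max(dis0)
  if (mx <= 0) stop("no separation: all dissimilarities are zero")
  agglomerate(dis0 / mx, "average")
}

#' Approach A2: 1 - p as the dissimilarity, no learning step
#'
#' Uses one minus the p-value of the pairwise test as the dissimilarity
#' (range \[0, 1\]) and applies average-linkage agglomeration.  For large,
#' well-separated cohorts the p-values underflow and nearly all entries are
#' indistinguishable from 1 at double precision, compressing the top of the
#' dendrogram.
#'
#' @param cohorts list of [combination_cohort()] objects.
#' @param test two-sample test (default log-rank).
#' @return list with `dis` (the 1 - p matrix) and `tree` (an `eaccd_tree`).
#' @export
approach_a2 <- function(cohorts, test = weight_schemes) {
  test <- match.arg(test, weight_schemes)
  n <- length(cohorts)
  if (n < 2) stop("need at least 2 cohorts")
  labels <- cohort_labels(cohorts)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      res <- weighted_two_sample_test(cohorts[[i]], cohorts[[j]], test)
      d[i, j] <- d[j, i] <- 1 - res$p_value
    }
  }
  list(dis = d, tree = agglomerate(d, "average"))
}

#' Covariate summaries per combination
#'
#' Mean raw tumor size and mean raw node count of each combination, with
#' min-max standardized versions across combinations (smallest mean maps to
#' 0, largest to 1).
#'
#' @param cohorts list of [combination_cohort()] objects whose covariates
#'   contain `tumor_size_cm` and `node_count`.
#' @return data frame with columns `label`, `t_hat`, `n_hat`, `t_hat_s`,
#'   `n_hat_s`.
#' @export
factor_summaries <- function(cohorts) {
  rows <- lapply(cohorts, function(ch) {
    if (is.null(ch$covariates) ||
        !all(c("tumor_size_cm", "node_count") %in% names(ch$covariates)))
      stop("cohort ", ch$label, " lacks raw covariates tumor_size_cm/node_count")
    data.frame(label = ch$label,
               t_hat = mean(ch$covariates$tumor_size_cm),
               n_hat = mean(ch$covariates$node_count))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  minmax <- function(x) {
    r <- range(x)
    if (diff(r) == 0) stop("covariate means are constant; cannot standardize")
    (x - r[1]) / diff(r)
  }
  out$t_hat_s <- minmax(out$t_hat)
  out$n_hat_s <- minmax(out$n_hat)
  out
}

a3_distance <- function(cohorts) {
  fs <- factor_summaries(cohorts)
  d <- abs(outer(fs$t_hat_s, fs$t_hat_s, "-")) +
       abs(outer(fs$n_hat_s, fs$n_hat_s, "-"))
  dimnames(d) <- list(fs$label, fs$label)
  mx <- max(d)
  if (mx <= 0) stop("zero maximum covariate distance")
  list(summaries = fs, dis = d / mx)
}

#' Approach A3: clustering on covariate means only
#'
#' Represents each combination by its mean raw tumor size and mean raw node
#' count, min-max standardizes both across combinations, takes the L1
#' distance, divides by the global maximum and applies average-linkage
#' agglomeration.  Survival times are never read, so combinations with
#' identical covariate distributions but different hazards get distance 0 —
#' the mechanism by which covariate-only clustering can mislead.
#'
#' @param cohorts list of [combination_cohort()] objects with raw covariates.
#' @return list with `summaries` (a [factor_summaries()] data frame), `dis`
#'   (the standardized distance matrix, max entry 1) and `tree`.
#' @export
approach_a3 <- function(cohorts) {
  a3 <- a3_distance(cohorts)
  c(a3, list(tree = agglomerate(a3$dis, "average")))
}

#' Approach A3*: learning step on top of the covariate distance
#'
#' Replaces the initial dissimilarity with A3's standardized covariate
#' distance, then runs the consensus-learning step and average-linkage
#' agglomeration as in the full pipeline.
#'
#' @param cohorts list of [combination_cohort()] objects with raw covariates.
#' @param config an [ensemble_config()].
#' @return list with `dis` (consensus matrix) and `tree`.
#' @export
approach_a3_star <- function(cohorts, config = ensemble_config()) {
  a3 <- a3_distance(cohorts)
  dis <- ensemble_dissimilarity(a3$dis, config)
  list(dis = dis, tree = agglomerate(dis, "average"))
}

#' Approach A4: direct PAM partitions of the standardized dissimilarity
#'
#' Standardizes the initial dissimilarity as in A1 and partitions it
#' directly with PAM (BUILD initialisation, the classical default) for each
#' requested number of clusters.
#'
#' @param dis0 initial dissimilarity matrix.
#' @param k_list numbers of clusters (default 2..11).
#' @return named list of [pam_partition()] results, one per k.
#' @export
approach_a4 <- function(dis0, k_list = 2:11) {
  validate_dissimilarity(dis0)
  mx <- max(dis0)
  if (mx <= 0) stop("no separation: all dissimilarities are zero")
  dA1s <- dis0 / mx
  out <- lapply(k_list, function(k) pam_partition(dA1s, k, init = "build"))
  names(out) <- paste0("k", k_list)
  out
}
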