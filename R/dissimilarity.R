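#' Validate a dissimilarity matrix
#'
#' Checks the invariants every pairwise dissimilarity in the pipeline must
#' satisfy: square, symmetric, zero diagonal, nonnegative; consensus
#' matrices additionally have all entries at most 1.
#'
#' @param d numeric matrix with row/column labels.
#' @param consensus if `TRUE` also require entries `<= 1`.
#' @return `d`, invisibly, after validation.
#' @export
validate_dissimilarity <- function(d, consensus = FALSE) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("not a square matrix")
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    stop("row and column labels must be present and identical")
  if (anyNA(d)) stop("missing entries")
  if (max(abs(d - t(d))) > 1e-8) stop("not symmetric")
  if (any(abs(diag(d)) > 0)) stop("nonzero diagonal")
  if (any(d < 0)) stop("negative entries")
  if (consensus && any(d > 1 + 1e-12)) stop("consensus entries must be <= 1")
  invisible(d)
}

#' Initial dissimilarity between combinations
#'
#' Entry (i, j) is the value of the chosen weighted two-sample survival test
#' statistic comparing cohort i with cohort j; the diagonal is zero.  The
#' statistic is nonnegative and unbounded above, so this matrix is *not* on a
#' \[0,1\] scale.  A degenerate pair (zero test variance, e.g. no events in the
#' pooled data) yields entry 0 and a warning naming the pair.
#'
#' @param cohorts list of at least two [combination_cohort()] objects.
#' @param test one of `"logrank"`, `"gehan_wilcoxon"`, `"tarone_ware"`.
#' @return symmetric labeled dissimilarity matrix.
#' @export
initial_dissimilarity <- function(cohorts, test = weight_schemes) {
  test <- match.arg(test, weight_schemes)
  n <- length(cohorts)
  if (n < 2) stop("need at least 2 cohorts")
  labels <- cohort_labels(cohorts)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      res <- weighted_two_sample_test(cohorts[[i]], cohorts[[j]], test)
      if (res$degenerate)
        warning(sprintf("degenerate test (zero variance) for pair %s / %s; dissimilarity set to 0",
                        labels[i], labels[j]))
      d[i, j] <- d[j, i] <- res$statistic
    }
  }
  validate_dissimilarity(d)
  d
}

#' Partition around medoids
#'
#' K-medoids partition of a dissimilarity matrix minimising the
#' within-cluster scatter \eqn{\sum_k \sum_{C(x_i)=k} dis(x_i, x_{i_k})},
#' the total dissimilarity of points to their cluster's medoid (reported
#' unscaled).  `init = "random"` draws k distinct medoids uniformly from R's
#' random number stream and then runs the SWAP local search; `init = "build"`
#' uses the greedy BUILD phase (the default initialisation of classical PAM
#' implementations) before SWAP.  Each accepted swap strictly decreases the
#' objective; points tied between equidistant medoids go to the lowest medoid
#' index, and a medoid always belongs to its own cluster.
#'
#' @param dis labeled dissimilarity matrix.
#' @param k number of clusters, 1..n.  `k = n` returns every point as its own
#'   medoid with objective 0; `k = 1` returns the row-sum argmin as medoid.
#' @param init `"random"` or `"build"`.
#' @param medoids optional integer vector of k initial medoid indices,
#'   overriding `init`.
#' @return object of class `pam_partition`: `assignment` (named cluster ids
#'   1..k), `medoids` (indices, ascending), `objective`,
#'   `objective_trace` (objective after initialisation and after each
#'   accepted swap).
#' @export
pam_partition <- function(dis, k, init = c("random", "build"), medoids = NULL) {
  init <- match.arg(init)
  validate_dissimilarity(dis)
  n <- nrow(dis)
  if (k < 1 || k > n) stop("k must be in 1..n")
  if (is.null(medoids) && init == "random")
    medoids <- sample.int(n, k)
  fit <- pam_fit(dis, k, as.integer(if (is.null(medoids)) integer(0) else medoids),
                 build = is.null(medoids))
  assignment <- fit$assignment
  names(assignment) <- rownames(dis)
  structure(list(assignment = assignment, medoids = fit$medoids,
                 objective = fit$objective,
                 objective_trace = fit$objective_trace, k = k),
            class = "pam_partition")
}

#' @export
print.pam_partition <- function(x, ...) {
  cat(sprintf("PAM partition: k = %d, objective = %.4g\n", x$k, x$objective))
  print(split(names(x$assignment), x$assignment))
  invisible(x)
}

#' Ensemble configuration
#'
#' Settings for the dissimilarity-learning step: the number of partitioning
#' runs `m`, the inclusive range `[k_min, k_max]` from which the number of
#' clusters K is drawn uniformly at each run, the collection of partitioning
#' procedures sampled uniformly per run (default: PAM with random medoid
#' initialisation only), and the RNG seed.
#'
#' @param m number of runs (the evaluation default is 10000).
#' @param k_min,k_max inclusive K range; `k_max = NULL` means n - 1, resolved
#'   when the ensemble runs.
#' @param partitioners nonempty list of functions `f(dis, k)` returning an
#'   integer cluster assignment of length n.
#' @param seed integer seed, or `NULL` to leave the RNG state alone.
#' @return an `ensemble_config` object.
#' @export
ensemble_config <- function(m = 10000, k_min = 2, k_max = NULL,
                            partitioners = list(pam_random_partitioner),
                            seed = NULL) {
  if (m < 1) stop("m must be >= 1")
  if (k_min < 2) stop("k_min must be >= 2")
  if (!is.null(k_max) && k_max < k_min) stop("need k_min <= k_max")
  if (length(partitioners) == 0) stop("need at least one partitioner")
  structure(list(m = as.integer(m), k_min = as.integer(k_min),
                 k_max = if (is.null(k_max)) NULL else as.integer(k_max),
                 partitioners = partitioners, seed = seed),
            class = "ensemble_config")
}

#' Default partitioner: PAM with random initial medoids
#'
#' @param dis dissimilarity matrix.
#' @param k number of clusters.
#' @return integer cluster assignment.
#' @export
pam_random_partitioner <- function(dis, k) {
  pam_partition(dis, k, init = "random")$assignment
}

#' Learnt (consensus) dissimilarity
#'
#' Runs the partitioning process `m` times.  Each run draws K uniformly from
#' `[k_min, k_max]`, draws one partitioner uniformly from the configured
#' collection, and partitions the combinations on the initial dissimilarity.
#' The learnt dissimilarity between combinations i and j is the fraction of
#' runs that do *not* assign them to the same cluster, so every entry lies in
#' \[0, 1\], the diagonal is 0 and the matrix is symmetric.  Reproducible from
#' `config$seed`.
#'
#' @param dis0 initial dissimilarity matrix.
#' @param config an [ensemble_config()].
#' @return consensus dissimilarity matrix (entries in \[0, 1\]).
#' @export
ensemble_dissimilarity <- function(dis0, config = ensemble_config()) {
  validate_dissimilarity(dis0)
  n <- nrow(dis0)
  k_max <- if (is.null(config$k_max)) n - 1L else config$k_max
  if (!(2 <= config$k_min && config$k_min <= k_max && k_max <= n - 1))
    stop("invalid K range: need 2 <= k_min <= k_max <= n - 1")
  if (!is.null(config$seed)) set.seed(config$seed)
  kk <- config$k_min:k_max
  np <- length(config$partitioners)
  sep <- matrix(0, n, n)
  for (l in seq_len(config$m)) {
    K <- if (length(kk) == 1L) kk else kk[sample.int(length(kk), 1L)]
    p <- config$partitioners[[if (np == 1L) 1L else sample.int(np, 1L)]]
    asg <- p(dis0, K)
    sep <- sep + outer(asg, asg, "!=")
  }
  d <- sep / config$m
  dimnames(d) <- dimnames(dis0)
  validate_dissimilarity(d, consensus = TRUE)
  d
}
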