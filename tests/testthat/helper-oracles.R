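# Independent oracles used by the test suite.  Each is a deliberately naive
# implementation kept separate from the package's code paths.

# Literal transcription of the weighted two-sample U/V sums: explicit loop
# over pooled event times, no vectorisation shared with the implementation.
oracle_weighted_test <- function(ta, ea, tb, eb, scheme) {
  pt <- c(ta, tb)
  pe <- c(ea, eb)
  tj <- sort(unique(pt[pe == 1]))
  U <- 0
  V <- 0
  for (t in tj) {
    n_j <- sum(pt >= t)
    d_j <- sum(pt == t & pe == 1)
    n_aj <- sum(ta >= t)
    d_aj <- sum(ta == t & ea == 1)
    w <- switch(scheme,
                logrank = 1,
                gehan_wilcoxon = n_j,
                tarone_ware = sqrt(n_j))
    U <- U + w * (d_aj - n_aj * d_j / n_j)
    if (n_j > 1)
      V <- V + w^2 * (n_aj / n_j) * (1 - n_aj / n_j) *
        ((n_j - d_j) / (n_j - 1)) * d_j
  }
  if (V <= 0) 0 else U^2 / V
}

# Exhaustive k-medoids optimum: enumerate every medoid subset.
oracle_pam_optimum <- function(d, k) {
  n <- nrow(d)
  best <- Inf
  sets <- utils::combn(n, k)
  for (i in seq_len(ncol(sets))) {
    cost <- sum(apply(d[, sets[, i], drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

# Small random censored cohort for property tests.
random_cohort <- function(n, hazard = 0.2, censor = 0.1, label = "X") {
  ev <- stats::rexp(n, hazard)
  cn <- stats::rexp(n, censor)
  combination_cohort(label, c(F1 = "1"),
                     time = pmin(ev, cn), event = as.integer(ev <= cn))
}

# Random dissimilarity matrix with continuous (tie-free) entries.
random_dissimilarity <- function(n) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2, 0.1, 2)
  d <- d + t(d)
  dimnames(d) <- list(paste0("x", seq_len(n)), paste0("x", seq_len(n)))
  d
}

# Clade signature of any merge structure with hclust-style fields.
clades_of <- function(merge, labels) {
  n <- length(labels)
  members <- vector("list", n - 1)
  get <- function(code) if (code < 0) labels[-code] else members[[code]]
  for (s in seq_len(n - 1))
    members[[s]] <- c(get(merge[s, 1]), get(merge[s, 2]))
  sort(vapply(members, function(m) paste(sort(m), collapse = ","), ""))
}

# Scenario in which T1N0 and T1N1 share the covariate distribution exactly
# (degenerate ranges; N0 and N1 both map to zero nodes) while their hazards
# differ tenfold.  Other N2-level combinations carry nonzero node counts so
# the node covariate still has spread across combinations.
identical_covariate_scenario <- function(seed = 33) {
  scenario_spec(
    factor_levels = list(T = 1:2, N = 0:2),
    group_of = c(T1N0 = 1, T1N1 = 2, T1N2 = 3, T2N0 = 3, T2N1 = 3, T2N2 = 3),
    hazard_of = c(0.005, 0.05, 0.02),
    n_of = 300,
    covariate_ranges = list(
      tumor_size_cm = list(factor = "T", integer = FALSE,
                           ranges = list(`1` = c(1, 1), `2` = c(4, 4))),
      node_count = list(factor = "N", integer = TRUE,
                        ranges = list(`0` = c(0, 0), `1` = c(0, 0),
                                      `2` = c(6, 10)))),
    seed = seed)
}

# Tiny planted scenario with two outcome groups over a 2 x 2 grid, used by
# several module tests; cheap to generate.
small_scenario <- function(seed = 5, n = 400, hazards = c(0.01, 0.08)) {
  scenario_spec(
    factor_levels = list(T = 1:2, N = 0:1),
    group_of = c(T1N0 = 1, T1N1 = 1, T2N0 = 2, T2N1 = 2),
    hazard_of = hazards, n_of = n, seed = seed)
}
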