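#' Stability of the learnt dissimilarity across repeated runs
#'
#' Repeats the consensus-learning step at each value of `m` with independent
#' seeds and quantifies how reproducible the resulting dendrograms are: the
#' fraction of repeat pairs sharing the same merge topology, the mean
#' pairwise cophenetic correlation, and the largest absolute difference
#' between consensus matrices.  Small `m` leaves the learnt dissimilarity
#' unconverged, so repeated runs with identical settings can produce visibly
#' different dendrograms; agreement approaches 1 as `m` grows.
#'
#' @param cohorts list of [combination_cohort()] objects.
#' @param m_values numbers of ensemble runs to profile (default the standard
#'   grid 10 .. 30000).
#' @param repeats independent repeats per `m`.
#' @param test,linkage settings for steps 1 and 3.
#' @param k_min,k_max K range (`k_max = NULL` means n - 1).
#' @param seed base seed; repeat r at the i-th m uses seed + 1000 * i + r.
#' @return data frame with one row per `m`: `m`, `repeats`,
#'   `topology_agreement` (fraction of identical-topology repeat pairs),
#'   `mean_cophenetic_cor`, `max_consensus_diff`.
#' @export
stability_experiment <- function(cohorts,
                                 m_values = c(10, 20, 50, 100, 500, 1000,
                                              5000, 10000, 20000, 30000),
                                 repeats = 3,
                                 test = "logrank", linkage = "average",
                                 k_min = 2, k_max = NULL, seed = 1) {
  dis0 <- initial_dissimilarity(cohorts, test)
  rows <- lapply(seq_along(m_values), function(i) {
    m <- m_values[i]
    runs <- lapply(seq_len(repeats), function(r) {
      cfg <- ensemble_config(m = m, k_min = k_min, k_max = k_max,
                             seed = seed + 1000L * i + r)
      dis <- ensemble_dissimilarity(dis0, cfg)
      list(dis = dis, tree = agglomerate(dis, linkage))
    })
    pairs <- utils::combn(repeats, 2)
    topo <- mean(apply(pairs, 2, function(p)
      same_topology(runs[[p[1]]]$tree, runs[[p[2]]]$tree)))
    ccor <- mean(apply(pairs, 2, function(p)
      cophenetic_correlation(runs[[p[1]]]$tree, runs[[p[2]]]$tree)))
    dmax <- max(apply(pairs, 2, function(p)
      max(abs(runs[[p[1]]]$dis - runs[[p[2]]]$dis))))
    data.frame(m = m, repeats = repeats, topology_agreement = topo,
               mean_cophenetic_cor = ccor, max_consensus_diff = dmax)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Adjusted Rand index between two cluster assignments
#'
#' Chance-corrected agreement between two partitions (1 = identical), via
#' [mclust::adjustedRandIndex()].
#'
#' @param a,b cluster membership vectors over the same items.
#' @return a single number, at most 1.
#' @export
adjusted_rand <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}
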