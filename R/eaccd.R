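#' Run the full ensemble clustering pipeline
#'
#' Executes the three steps in order: (1) initial dissimilarity from the
#' chosen weighted two-sample survival test; (2) learnt (consensus)
#' dissimilarity from `config$m` randomized PAM runs with K drawn uniformly
#' from `[k_min, k_max]`; (3) agglomerative clustering of the learnt
#' dissimilarity with the chosen linkage.  All intermediates are returned
#' for inspection and serialization.
#'
#' @param cohorts list of [combination_cohort()] objects (the combinations).
#' @param test two-sample test for step 1 (default log-rank).
#' @param config an [ensemble_config()]; `k_max = NULL` resolves to n - 1,
#'   mirroring the standard evaluation setting (K1 = 2, K2 = n - 1).
#' @param linkage linkage for step 3 (default average).
#' @return object of class `eaccd_fit`: `dis0` (initial dissimilarity),
#'   `dis` (consensus dissimilarity), `tree` (the dendrogram,
#'   an `eaccd_tree`), plus the settings used.
#' @examples
#' cohorts <- standard_fixture(seed = 1)
#' fit <- run_eaccd(cohorts, config = ensemble_config(m = 200, seed = 1))
#' cut_tree(fit$tree, 4)
#' @export
run_eaccd <- function(cohorts, test = weight_schemes,
                      config = ensemble_config(),
                      linkage = c("average", "complete", "single")) {
  test <- match.arg(test, weight_schemes)
  linkage <- match.arg(linkage)
  dis0 <- initial_dissimilarity(cohorts, test)
  dis <- ensemble_dissimilarity(dis0, config)
  tree <- agglomerate(dis, linkage)
  structure(list(dis0 = dis0, dis = dis, tree = tree, test = test,
                 linkage = linkage, config = config),
            class = "eaccd_fit")
}

#' @export
print.eaccd_fit <- function(x, ...) {
  n <- nrow(x$dis)
  cat(sprintf("Ensemble clustering of %d combinations\n", n))
  cat(sprintf("  test: %s | m = %d | K in [%d, %d] | linkage: %s\n",
              x$test, x$config$m, x$config$k_min,
              if (is.null(x$config$k_max)) n - 1L else x$config$k_max,
              x$linkage))
  cat(sprintf("  consensus dissimilarity range (off-diagonal): %.3f .. %.3f\n",
              min(x$dis[upper.tri(x$dis)]), max(x$dis[upper.tri(x$dis)])))
  print(x$tree)
  invisible(x)
}
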