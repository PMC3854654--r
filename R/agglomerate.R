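#' Agglomerative hierarchical clustering of a dissimilarity matrix
#'
#' Standard bottom-up agglomeration under the Lance-Williams update for the
#' chosen linkage (average: size-weighted mean of cross-pair dissimilarities;
#' complete: maximum; single: minimum).  Deterministic given the input: when
#' several candidate merges share the minimal linkage value, the pair whose
#' clusters contain the lowest leaf indices (lexicographically) is merged —
#' a fixed tie-break needed to compare tree topologies across seeds.
#'
#' @param dis labeled dissimilarity matrix, n >= 2.
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return object of class `eaccd_tree`, compatible with [stats::hclust]
#'   via [as.hclust()]: components `merge` (hclust-style merge matrix),
#'   `height` (non-decreasing merge heights), `order`, `labels`, `method`.
#' @export
agglomerate <- function(dis, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  validate_dissimilarity(dis)
  n <- nrow(dis)
  if (n < 2) stop("need at least 2 items")

  D <- dis
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  code <- -seq_len(n)        # hclust codes: negative leaf, positive merge row
  minleaf <- seq_len(n)      # lowest leaf index in each cluster (tie-break)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (s in seq_len(n - 1)) {
    # scan active pairs in lexicographic order of (minleaf_i, minleaf_j);
    # strict < keeps the first minimum, i.e. the lowest-label tied pair
    idx <- which(active)
    idx <- idx[order(minleaf[idx])]
    best <- Inf; bi <- 0L; bj <- 0L
    for (a in seq_len(length(idx) - 1)) {
      for (b in (a + 1):length(idx)) {
        i <- idx[a]; j <- idx[b]
        if (D[i, j] < best) { best <- D[i, j]; bi <- i; bj <- j }
      }
    }
    # record merge; hclust convention orders each row (singletons first)
    ca <- code[bi]; cb <- code[bj]
    merge[s, ] <- if (ca < cb) c(ca, cb) else c(cb, ca)
    height[s] <- best

    # Lance-Williams update into slot bi; retire bj
    others <- setdiff(idx, c(bi, bj))
    upd <- switch(linkage,
      average  = (size[bi] * D[bi, others] + size[bj] * D[bj, others]) /
                 (size[bi] + size[bj]),
      complete = pmax(D[bi, others], D[bj, others]),
      single   = pmin(D[bi, others], D[bj, others]))
    D[bi, others] <- upd
    D[others, bi] <- upd
    size[bi] <- size[bi] + size[bj]
    minleaf[bi] <- min(minleaf[bi], minleaf[bj])
    code[bi] <- s
    active[bj] <- FALSE
  }

  leaf_order <- function(node) {
    if (node < 0) return(-node)
    c(leaf_order(merge[node, 1]), leaf_order(merge[node, 2]))
  }
  structure(list(merge = merge, height = height,
                 order = leaf_order(n - 1L), labels = rownames(dis),
                 method = linkage, dist.method = "dissimilarity"),
            class = "eaccd_tree")
}

#' @export
as.hclust.eaccd_tree <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$method,
                 call = match.call(), dist.method = x$dist.method),
            class = "hclust")
}

#' @export
print.eaccd_tree <- function(x, ...) {
  cat(sprintf("Merge tree (%s linkage): %d leaves, heights %.3g .. %.3g\n",
              x$method, length(x$labels), min(x$height), max(x$height)))
  invisible(x)
}

#' @param x an `eaccd_tree`.
#' @param ylab,... passed to [stats::plot.hclust()].
#' @rdname agglomerate
#' @export
plot.eaccd_tree <- function(x, ylab = "dissimilarity", ...) {
  graphics::plot(as.hclust(x), ylab = ylab, ...)
  invisible(x)
}

#' Cut a merge tree into k clusters
#'
#' Undoes the last k - 1 merges, returning the k clusters present at that
#' point (via [stats::cutree]).
#'
#' @param tree an `eaccd_tree`.
#' @param k number of clusters, 1..n_leaves.
#' @return named integer vector of cluster memberships.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$labels)
  if (k < 1 || k > n) stop("k must be in 1..n_leaves")
  stats::cutree(as.hclust(tree), k = k)
}

#' Cophenetic distance matrix of a merge tree
#'
#' Entry (i, j) is the height at which leaves i and j first belong to the
#' same cluster.  The result is ultrametric.
#'
#' @param tree an `eaccd_tree`.
#' @return symmetric labeled matrix of cophenetic distances.
#' @export
cophenetic_matrix <- function(tree) {
  m <- as.matrix(stats::cophenetic(as.hclust(tree)))
  m[tree$labels, tree$labels]
}

#' Clade set of a merge tree
#'
#' The topology of a dendrogram, encoded as the set of leaf-label sets of
#' its internal nodes.  Two trees have the same merging pattern iff their
#' clade sets are equal, regardless of merge heights.
#'
#' @param tree an `eaccd_tree`.
#' @return character vector, one sorted comma-joined label set per internal
#'   node, itself sorted.
#' @export
tree_clades <- function(tree) {
  n <- length(tree$labels)
  members <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    get <- function(code) if (code < 0) tree$labels[-code] else members[[code]]
    members[[s]] <- c(get(tree$merge[s, 1]), get(tree$merge[s, 2]))
  }
  sort(vapply(members, function(m) paste(sort(m), collapse = ","), ""))
}

#' Do two merge trees share the same topology?
#'
#' @param a,b `eaccd_tree` objects over the same leaf labels.
#' @return `TRUE` iff the clade sets coincide.
#' @export
same_topology <- function(a, b) {
  identical(tree_clades(a), tree_clades(b))
}

#' Cophenetic correlation between two merge trees
#'
#' Pearson correlation of the lower-triangle cophenetic distances, a
#' standard quantitative measure of dendrogram agreement.
#'
#' @param a,b `eaccd_tree` objects over the same leaf labels.
#' @return correlation in \[-1, 1\].
#' @export
cophenetic_correlation <- function(a, b) {
  ma <- cophenetic_matrix(a)
  mb <- cophenetic_matrix(b)[rownames(ma), colnames(ma)]
  stats::cor(ma[lower.tri(ma)], mb[lower.tri(mb)])
}
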