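# Readers and writers for the pipeline's plain-text artifacts: the canonical
# patient CSV, labeled dissimilarity CSVs, Newick and JSON tree
# serializations, cluster assignment tables and the reproducibility manifest.

#' Load patient records from a delimited file
#'
#' Reads a header-ed CSV of patient-level records and validates every row:
#' the observed time must parse as a nonnegative real, the event indicator
#' must be 0 or 1, and factor levels must be present.  Rows failing any check
#' are rejected with a warning reporting their count and line numbers (an
#' explicit complete-records inclusion rule), and returned in the
#' `"rejected"` attribute.
#'
#' @param path CSV file path.
#' @param factors factor column names (default `T_level`, `N_level`).
#' @param time_col,event_col observed-time and event-indicator column names.
#' @param covariate_cols raw covariate columns to retain, if present.
#' @param sep field separator (default comma).
#' @return data frame of valid rows, with attribute `rejected` (a data frame
#'   of line numbers and reasons, possibly empty).
#' @export
load_patients <- function(path, factors = c("T_level", "N_level"),
                          time_col = "time_months", event_col = "event",
                          covariate_cols = c("tumor_size_cm", "node_count"),
                          sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  covariate_cols <- intersect(covariate_cols, names(raw))
  needed <- c(factors, time_col, event_col)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))

  time <- suppressWarnings(as.numeric(raw[[time_col]]))
  event <- suppressWarnings(as.numeric(raw[[event_col]]))
  bad_time <- is.na(time) | time < 0
  bad_event <- is.na(event) | !(event %in% c(0, 1))
  bad_factor <- Reduce(`|`, lapply(factors, function(f)
    is.na(raw[[f]]) | !nzchar(raw[[f]])))
  bad_cov <- if (length(covariate_cols)) {
    Reduce(`|`, lapply(covariate_cols, function(cv)
      is.na(suppressWarnings(as.numeric(raw[[cv]])))))
  } else rep(FALSE, nrow(raw))

  bad <- bad_time | bad_event | bad_factor | bad_cov
  reason <- character(sum(bad))
  if (any(bad)) {
    reason <- apply(cbind(bad_time, bad_event, bad_factor, bad_cov)[bad, , drop = FALSE],
                    1, function(r) paste(c("time", "event", "factor", "covariate")[r],
                                         collapse = "+"))
  }
  rejected <- data.frame(line = which(bad) + 1L, reason = reason)  # +1: header
  if (nrow(rejected))
    warning(sprintf("rejected %d row(s) with invalid fields (lines %s)",
                    nrow(rejected), paste(rejected$line, collapse = ", ")))

  out <- raw[!bad, needed, drop = FALSE]
  out[[time_col]] <- time[!bad]
  out[[event_col]] <- as.integer(event[!bad])
  for (cv in covariate_cols) out[[cv]] <- as.numeric(raw[[cv]][!bad])
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write patient records to the canonical CSV
#'
#' Numeric columns are written with full double precision so that a
#' write-then-load round trip reproduces the cohorts exactly.
#'
#' @param data patient-level data frame (e.g. from [cohorts_to_data()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_patients <- function(data, path) {
  out <- data
  for (nm in names(out))
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a labeled dissimilarity matrix as CSV
#'
#' Square layout with combination labels as both header row and first
#' column; entries are written with 6 decimal places.
#'
#' @param d labeled dissimilarity matrix.
#' @param path CSV path.
#' @return `path` (write) or the matrix (read).
#' @export
write_dissimilarity <- function(d, path) {
  validate_dissimilarity(d)
  out <- as.data.frame(formatC(d, format = "f", digits = 6))
  out <- cbind(label = rownames(d), out)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dissimilarity
#' @export
read_dissimilarity <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw[[1]]
  storage.mode(m) <- "double"
  validate_dissimilarity(m)
  m
}

#' Serialize a merge tree to Newick
#'
#' Converts the tree to a rooted phylogram via [ape::as.phylo()] (branch
#' lengths derived from merge heights, written at full precision).
#'
#' @param tree an `eaccd_tree`.
#' @param path output file; `NULL` returns the Newick string.
#' @return the Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(as.hclust(tree))
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Serialize a merge tree to a JSON merge list
#'
#' One object per merge, from first to last: the member labels of the two
#' sides and the merge height.
#'
#' @param tree an `eaccd_tree`.
#' @param path output file; `NULL` returns the JSON string.
#' @return the JSON string, invisibly when written to file.
#' @export
write_tree_json <- function(tree, path = NULL) {
  n <- length(tree$labels)
  members <- vector("list", n - 1)
  get <- function(code) if (code < 0) tree$labels[-code] else members[[code]]
  merges <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    left <- get(tree$merge[s, 1])
    right <- get(tree$merge[s, 2])
    members[[s]] <- c(left, right)
    merges[[s]] <- list(left = left, right = right, height = tree$height[s])
  }
  js <- jsonlite::toJSON(merges, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' Write all artifacts of a pipeline run
#'
#' Writes the initial and consensus dissimilarity CSVs, the dendrogram in
#' Newick and JSON, cluster assignments for each requested cut, and a JSON
#' manifest recording the settings, seed and library versions, so a run can
#' be reproduced bit for bit.
#'
#' @param fit an `eaccd_fit` from [run_eaccd()].
#' @param dir output directory (created if absent).
#' @param cuts integer vector of cluster counts to cut the tree at.
#' @return named character vector of file paths, invisibly.
#' @export
write_run_artifacts <- function(fit, dir, cuts = c(2, 4)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    dis0 = file.path(dir, "dis0.csv"),
    consensus = file.path(dir, "consensus.csv"),
    newick = file.path(dir, "tree.nwk"),
    tree_json = file.path(dir, "tree.json"),
    assignments = file.path(dir, "assignments.csv"),
    manifest = file.path(dir, "manifest.json"))
  write_dissimilarity(fit$dis0, paths["dis0"])
  write_dissimilarity(fit$dis, paths["consensus"])
  write_newick(fit$tree, paths["newick"])
  write_tree_json(fit$tree, paths["tree_json"])

  asg <- data.frame(label = fit$tree$labels)
  for (k in cuts) asg[[paste0("k", k)]] <- unname(cut_tree(fit$tree, k)[asg$label])
  utils::write.csv(asg, paths["assignments"], row.names = FALSE, quote = FALSE)

  n <- nrow(fit$dis)
  manifest <- list(
    test = fit$test, linkage = fit$linkage,
    m = fit$config$m, k_min = fit$config$k_min,
    k_max = if (is.null(fit$config$k_max)) n - 1L else fit$config$k_max,
    seed = fit$config$seed, n_combinations = n, cuts = cuts,
    versions = list(
      r = as.character(getRversion()),
      eaccd = as.character(utils::packageVersion("eaccd")),
      survival = as.character(utils::packageVersion("survival")),
      ape = as.character(utils::packageVersion("ape"))))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
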