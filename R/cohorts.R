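#' Combination cohorts
#'
#' A *combination* is the set of patients sharing one level of every
#' prognostic factor (e.g. all patients with tumor level T2 and nodal level
#' N1).  A `combination_cohort` holds the survival records of one
#' combination: observed times, event indicators (1 = event, 0 =
#' right-censored) and optional raw continuous covariates (tumor size in cm,
#' involved-node count) needed by the covariate-only comparison approach.
#'
#' @param label combination label, e.g. `"T2N1"`.
#' @param levels named vector of factor levels defining the combination.
#' @param time nonnegative observed times (censored or uncensored).
#' @param event 0/1 event indicators, same length as `time`.
#' @param covariates optional data frame of raw covariates, one row per
#'   patient.
#' @return an object of class `combination_cohort`.
#' @export
combination_cohort <- function(label, levels, time, event, covariates = NULL) {
  time <- as.numeric(time)
  event <- as.integer(event)
  if (length(time) == 0L) stop("empty cohort")
  if (length(event) != length(time)) stop("time and event lengths differ")
  if (anyNA(time) || any(time < 0)) stop("times must be nonnegative and non-missing")
  if (anyNA(event) || !all(event %in% c(0L, 1L))) stop("event must be 0 or 1")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(time)) stop("covariates row count must match time")
  }
  structure(
    list(label = as.character(label), levels = levels, time = time,
         event = event, covariates = covariates),
    class = "combination_cohort"
  )
}

#' @export
print.combination_cohort <- function(x, ...) {
  cat(sprintf("Combination %s: %d patients, %d events (%.1f%% censored)\n",
              x$label, length(x$time), sum(x$event),
              100 * mean(x$event == 0L)))
  invisible(x)
}

#' Group patient records into combination cohorts
#'
#' Splits a patient-level table into one [combination_cohort()] per observed
#' combination of factor levels.  Labels are built by concatenating each
#' factor's name prefix with its level code (column `"T_level"` with value 2
#' contributes `"T2"`), matching the field's TxNy convention.
#'
#' @param data data frame with one row per patient.
#' @param factors character vector of factor column names (default the
#'   canonical `T_level`, `N_level`).
#' @param time_col,event_col names of the observed-time and event-indicator
#'   columns.
#' @param covariate_cols optional character vector of raw covariate columns
#'   carried into each cohort (e.g. `tumor_size_cm`, `node_count`).
#' @return named list of `combination_cohort` objects, ordered by factor
#'   levels.
#' @export
as_cohorts <- function(data, factors = c("T_level", "N_level"),
                       time_col = "time_months", event_col = "event",
                       covariate_cols = intersect(c("tumor_size_cm", "node_count"),
                                                  names(data))) {
  missing_cols <- setdiff(c(factors, time_col, event_col, covariate_cols), names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  prefix <- sub("_level$", "", factors)
  lab <- do.call(paste0, c(Map(function(p, f) paste0(p, data[[f]]), prefix, factors)))
  key <- do.call(order, c(unname(data[factors]), list(lab)))
  data <- data[key, , drop = FALSE]
  lab <- lab[key]
  out <- lapply(split(seq_len(nrow(data)), factor(lab, levels = unique(lab))),
                function(idx) {
    lv <- vapply(factors, function(f) as.character(data[[f]][idx[1]]), "")
    names(lv) <- prefix
    combination_cohort(
      label = lab[idx[1]], levels = lv,
      time = data[[time_col]][idx], event = data[[event_col]][idx],
      covariates = if (length(covariate_cols))
        data[idx, covariate_cols, drop = FALSE] else NULL)
  })
  out
}

#' Flatten cohorts back to a patient-level table
#'
#' Inverse of [as_cohorts()]: one row per patient with factor level columns,
#' covariates (if present), observed time and event indicator.
#'
#' @param cohorts list of [combination_cohort()] objects.
#' @return data frame in the canonical column layout
#'   `T_level,N_level,tumor_size_cm,node_count,time_months,event`.
#' @export
cohorts_to_data <- function(cohorts) {
  stopifnot(length(cohorts) >= 1)
  do.call(rbind, lapply(cohorts, function(ch) {
    n <- length(ch$time)
    fac <- as.data.frame(lapply(ch$levels, rep, n), check.names = FALSE)
    names(fac) <- paste0(names(ch$levels), "_level")
    df <- fac
    if (!is.null(ch$covariates)) df <- cbind(df, ch$covariates)
    df$time_months <- ch$time
    df$event <- ch$event
    rownames(df) <- NULL
    df
  }))
}

cohort_labels <- function(cohorts) {
  unname(vapply(cohorts, function(ch) ch$label, ""))
}
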