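# Synthetic survival cohorts with planted outcome groups.  The generator
# emulates the shape of a registry extract of breast-cancer cases: a 3-level
# tumor-size factor crossed with a 4-level nodal-status factor gives 12
# combinations, each combination belongs to one latent outcome group with its
# own exponential hazard, follow-up is right-censored by an exponential
# dropout process truncated at an administrative cutoff, and raw covariates
# (tumor size in cm, involved-node count) are sampled uniformly within each
# level's clinical range.

#' Default raw-covariate sampling ranges
#'
#' Tumor size per T level follows the clinical category bounds (T1 <= 2 cm,
#' 2 < T2 <= 5 cm, T3 > 5 cm, capped at 15 cm); node counts per N level are
#' 0, 1-3, 4-10 and more than 10 (capped at 30).
#'
#' @return list describing each covariate: the factor it tracks, the
#'   per-level (low, high) ranges and whether values are integer counts.
#' @export
default_covariate_ranges <- function() {
  list(
    tumor_size_cm = list(
      factor = "T", integer = FALSE,
      ranges = list(`1` = c(0.2, 2), `2` = c(2, 5), `3` = c(5, 15))),
    node_count = list(
      factor = "N", integer = TRUE,
      ranges = list(`0` = c(0, 0), `1` = c(1, 3), `2` = c(4, 10),
                    `3` = c(11, 30)))
  )
}

#' Scenario specification for the cohort generator
#'
#' @param factor_levels named list of level codes per factor; the default
#'   is the 3 x 4 grid of tumor levels 1..3 and nodal levels 0..3 whose
#'   combinations are labeled T1N0 .. T3N3.
#' @param group_of named integer vector mapping every combination label to a
#'   latent outcome group id.
#' @param hazard_of exponential event rate per month for each group id
#'   (indexed by group id).
#' @param hazard_jitter named multiplier per combination applied to its
#'   group's rate (default 1 for all).  Real registry combinations in the
#'   same prognostic group have similar, never identical, survival; a mild
#'   within-group spread reproduces that.
#' @param n_of cohort size per combination: a single integer recycled to all
#'   combinations, or a named vector keyed by label.
#' @param censor_rate exponential dropout rate per month (0 disables random
#'   censoring).
#' @param admin_cutoff administrative follow-up cutoff in months (`Inf`
#'   disables it); observation stops at the earlier of dropout and cutoff.
#' @param covariate_ranges see [default_covariate_ranges()]; `NULL` disables
#'   covariate sampling.
#' @param seed integer RNG seed.
#' @return a `scenario_spec` object.
#' @export
scenario_spec <- function(factor_levels = list(T = 1:3, N = 0:3),
                          group_of, hazard_of, hazard_jitter = NULL,
                          n_of = 500,
                          censor_rate = 0.008, admin_cutoff = 132,
                          covariate_ranges = default_covariate_ranges(),
                          seed = 1) {
  grid <- expand.grid(rev(factor_levels), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(factor_levels)), drop = FALSE]
  labels <- apply(grid, 1, function(r)
    paste0(names(factor_levels), r, collapse = ""))
  grid <- grid[order(labels), , drop = FALSE]
  labels <- sort(labels)
  if (!all(labels %in% names(group_of)))
    stop("group_of must map every combination: missing ",
         paste(setdiff(labels, names(group_of)), collapse = ", "))
  if (!all(group_of[labels] %in% seq_along(hazard_of)))
    stop("hazard_of must cover every group id used in group_of")
  if (any(hazard_of <= 0)) stop("hazard_of: all rates must be > 0")
  if (censor_rate < 0) stop("censor_rate must be >= 0")
  if (length(n_of) == 1L && is.null(names(n_of))) {
    n_of <- stats::setNames(rep(as.integer(n_of), length(labels)), labels)
  }
  if (!all(labels %in% names(n_of))) stop("n_of must cover every combination")
  if (any(n_of < 1)) stop("n_of: all cohort sizes must be >= 1")
  if (is.null(hazard_jitter))
    hazard_jitter <- stats::setNames(rep(1, length(labels)), labels)
  if (!all(labels %in% names(hazard_jitter)))
    stop("hazard_jitter must cover every combination")
  if (any(hazard_jitter <= 0)) stop("hazard_jitter: multipliers must be > 0")
  structure(list(factor_levels = factor_levels, grid = grid, labels = labels,
                 group_of = group_of[labels], hazard_of = hazard_of,
                 hazard_jitter = hazard_jitter[labels],
                 n_of = n_of[labels], censor_rate = censor_rate,
                 admin_cutoff = admin_cutoff,
                 covariate_ranges = covariate_ranges, seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Generate combination cohorts from a scenario
#'
#' For each combination: event times are Exponential with its group's
#' hazard; censoring times are the minimum of an Exponential dropout time
#' and the administrative cutoff; the observed time is the smaller of event
#' and censoring time and the event indicator records which came first.
#' Raw covariates are sampled uniformly within the combination's level
#' ranges.  Deterministic given `spec$seed`.
#'
#' @param spec a [scenario_spec()].
#' @return named list of [combination_cohort()] objects, in label order.
#' @export
generate_cohorts <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  cohorts <- vector("list", length(spec$labels))
  names(cohorts) <- spec$labels
  for (i in seq_along(spec$labels)) {
    lab <- spec$labels[i]
    n <- spec$n_of[[lab]]
    haz <- spec$hazard_of[spec$group_of[[lab]]] * spec$hazard_jitter[[lab]]
    t_event <- stats::rexp(n, rate = haz)
    t_cens <- if (spec$censor_rate > 0)
      stats::rexp(n, rate = spec$censor_rate) else rep(Inf, n)
    t_cens <- pmin(t_cens, spec$admin_cutoff)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    levels <- vapply(seq_along(spec$factor_levels),
                     function(f) as.character(spec$grid[i, f]), "")
    names(levels) <- names(spec$factor_levels)
    covariates <- NULL
    if (!is.null(spec$covariate_ranges)) {
      covariates <- as.data.frame(lapply(spec$covariate_ranges, function(cv) {
        rng <- cv$ranges[[levels[[cv$factor]]]]
        x <- stats::runif(n, rng[1], rng[2])
        if (cv$integer) round(x) else x
      }))
    }
    cohorts[[i]] <- combination_cohort(lab, levels, time, event, covariates)
  }
  cohorts
}

#' Groups planted in the standard fixture
#'
#' Four latent outcome groups over the 12 T x N combinations, deliberately
#' unequal in size (1, 3, 2 and 6 members) and cutting across the factor
#' grid, as prognostic groups do in practice: a small tumor with many
#' positive nodes can fare like a large tumor with few, and the
#' poor-prognosis group collects many combinations whose survival forms a
#' gradient rather than a tie.
#'
#' @return named integer vector: combination label -> group id (1 = best
#'   prognosis, 4 = worst).
#' @export
standard_fixture_groups <- function() {
  c(T1N0 = 1,
    T1N1 = 2, T2N0 = 2, T3N0 = 2,
    T1N2 = 3, T2N1 = 3,
    T1N3 = 4, T2N2 = 4, T2N3 = 4, T3N1 = 4, T3N2 = 4, T3N3 = 4)
}

#' The canonical 12-combination synthetic fixture
#'
#' The package's standard end-to-end scenario: the 3 x 4 T x N grid, four
#' planted outcome groups of sizes 1 / 3 / 2 / 6 (see
#' [standard_fixture_groups()]).  Every combination has its own monthly
#' hazard — similar within a group, with a clear gap between groups — since
#' real registry combinations are never exactly tied: group 2 spreads mildly
#' around 0.006, group 3 around 0.012, and the six poor-prognosis
#' combinations form a gradient from 0.035 to 0.073.  Each combination has
#' 1000 patients, follow-up is censored by exponential dropout at
#' 0.008/month truncated at 132 months, and covariates are sampled within
#' the clinical level ranges.
#'
#' `inflate = TRUE` gives the oversized-combination variant that emulates the
#' situation driving approach A1's size sensitivity: T1N0 carries 20 times
#' more patients than any other combination *and* a markedly better hazard
#' (0.0005/month, about 94% survival at 10 years — oversized registry
#' combinations are typically also the earliest-stage, best-prognosis ones).
#' Both ingredients are needed: a two-sample test statistic grows with sample
#' size only where a true difference exists, so an oversized combination with
#' a hazard identical to its neighbors' would not reproduce the effect.
#' `equalize_inflated = TRUE` keeps the better T1N0 hazard but restores its
#' cohort size to 1000 — the "sizes reduced to a comparable quantity"
#' comparator under which the effect disappears.
#'
#' @param seed RNG seed (default 101).
#' @param inflate if `TRUE`, give T1N0 20000 patients and its own better
#'   hazard.
#' @param equalize_inflated if `TRUE`, keep T1N0's distinct better hazard
#'   but with 1000 patients.
#' @return named list of 12 [combination_cohort()] objects.
#' @export
standard_fixture <- function(seed = 101, inflate = FALSE,
                             equalize_inflated = FALSE) {
  groups <- standard_fixture_groups()
  # Per-combination monthly hazards: within-group spreads are mild and
  # clearly smaller than the between-group gaps.  Spacings within a group
  # are deliberately unequal (tight sub-pairs separated by larger, unequal
  # gaps): real survival curves come at staggered distances, and staggered
  # gaps keep the fine merge order identifiable instead of tie-ridden.
  rate <- c(T1N0 = 0.0016,
            T1N1 = 0.0050, T2N0 = 0.0055, T3N0 = 0.0068,
            T1N2 = 0.0120, T2N1 = 0.0140,
            T1N3 = 0.0350, T2N2 = 0.0370, T2N3 = 0.0400,
            T3N1 = 0.0423, T3N2 = 0.0540, T3N3 = 0.0570)
  n_of <- stats::setNames(rep(4000L, 12), names(groups))
  if (inflate || equalize_inflated) {
    # the oversized-combination variant: T1N0 is both far better (0.0005/month,
    # ~94% ten-year survival) and, unless equalized, 20x larger
    rate["T1N0"] <- 0.0005
    if (!equalize_inflated) n_of["T1N0"] <- 80000L
  }
  # group base rates are carried by hazard_of; per-combination rates are
  # expressed as multipliers of their group's base
  base <- c(0.0018, 0.0058, 0.0130, 0.0460)
  jitter <- rate / base[groups[names(rate)]]
  generate_cohorts(scenario_spec(
    group_of = groups, hazard_of = base, hazard_jitter = jitter,
    n_of = n_of, censor_rate = 0.008, admin_cutoff = 132,
    seed = seed))
}
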