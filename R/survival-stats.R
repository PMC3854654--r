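#' Kaplan-Meier survival curve for one cohort
#'
#' Product-limit estimate of the survival function from right-censored data,
#' computed with [survival::survfit()].  Steps occur only at uncensored event
#' times; censored observations reduce the risk set but create no step.
#' Censored observations tied with an event time are treated as still at risk
#' at that time (the standard convention).
#'
#' @param time a [combination_cohort()], or a numeric vector of observed
#'   times.
#' @param event 0/1 event indicators (ignored when `time` is a cohort).
#' @return an object of class `km_curve` with components `time` (strictly
#'   increasing event times), `surv` (survival probabilities, non-increasing,
#'   starting below 1 at the first event time) and `n` (number of subjects).
#'   With no events the curve is identically 1 and `time` is empty.
#' @export
km_estimate <- function(time, event = NULL) {
  if (inherits(time, "combination_cohort")) {
    event <- time$event
    time <- time$time
  }
  if (length(time) == 0L) stop("empty cohort")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  structure(list(time = fit$time[keep], surv = fit$surv[keep], n = length(time)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d event times\n",
              x$n, length(x$time)))
  invisible(x)
}

#' Minimal Kaplan-Meier step plot
#'
#' @param x a `km_curve`.
#' @param xlab,ylab,... passed to [graphics::plot.default()].
#' @return `x`, invisibly.
#' @export
plot.km_curve <- function(x, xlab = "time (months)",
                          ylab = "survival probability", ...) {
  graphics::plot(c(0, x$time), c(1, x$surv), type = "s", ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Median survival time of a Kaplan-Meier curve
#'
#' Smallest event time at which the estimated survival drops to 0.5 or below;
#' `Inf` if the curve never reaches 0.5.
#'
#' @param curve a `km_curve`.
#' @return a single number (months, on the input time scale).
#' @export
km_median <- function(curve) {
  i <- which(curve$surv <= 0.5)
  if (length(i) == 0L) Inf else curve$time[min(i)]
}

weight_schemes <- c("logrank", "gehan_wilcoxon", "tarone_ware")

#' Weighted two-sample survival test
#'
#' Compares the survival experience of two groups with a weighted log-rank
#' family statistic.  Over the pooled distinct event times \eqn{t_j} with
#' \eqn{d_j} pooled events, \eqn{n_j} pooled subjects at risk and
#' \eqn{d_{aj}}, \eqn{n_{aj}} the corresponding counts in group a:
#' \deqn{U = \sum_j w_j (d_{aj} - n_{aj} d_j / n_j)}
#' \deqn{V = \sum_j w_j^2 \frac{n_{aj}}{n_j}\left(1-\frac{n_{aj}}{n_j}\right)
#'       \frac{n_j-d_j}{n_j-1} d_j}
#' with a zero variance contribution whenever \eqn{n_j \le 1}.  The statistic
#' is the chi-square form \eqn{U^2/V} (nonnegative, 1 df) and the p-value its
#' upper chi-square tail.  Weights: \eqn{w_j = 1} (log-rank), \eqn{w_j = n_j}
#' (Gehan-Wilcoxon), \eqn{w_j = \sqrt{n_j}} (Tarone-Ware).
#'
#' When the pooled data contain no events (or the variance otherwise
#' vanishes) the statistic is defined as 0 with p-value 1 and the result is
#' flagged degenerate.
#'
#' @param group_a,group_b [combination_cohort()] objects, or lists with
#'   `time` and `event` components.
#' @param weight_scheme one of `"logrank"`, `"gehan_wilcoxon"`,
#'   `"tarone_ware"`.
#' @return an object of class `surv_test`: `statistic` (nonnegative),
#'   `p_value`, `weight_scheme`, `degenerate` flag.
#' @export
weighted_two_sample_test <- function(group_a, group_b,
                                     weight_scheme = weight_schemes) {
  weight_scheme <- match.arg(weight_scheme, weight_schemes)
  ta <- group_a$time; ea <- group_a$event
  tb <- group_b$time; eb <- group_b$event
  if (length(ta) == 0L || length(tb) == 0L) stop("empty group")

  pt <- c(ta, tb)
  pe <- c(ea, eb)
  tj <- sort(unique(pt[pe == 1L]))
  if (length(tj) == 0L) {
    return(structure(list(statistic = 0, p_value = 1,
                          weight_scheme = weight_scheme, degenerate = TRUE),
                     class = "surv_test"))
  }
  # at-risk counts via sorted search: n_j = #{x >= t_j}
  at_risk <- function(x) length(x) - findInterval(tj, sort(x), left.open = TRUE)
  n_j <- at_risk(pt)
  n_aj <- at_risk(ta)
  d_j <- tabulate(match(pt[pe == 1L], tj), nbins = length(tj))
  d_aj <- tabulate(match(ta[ea == 1L], tj), nbins = length(tj))

  w <- switch(weight_scheme,
              logrank = rep(1, length(tj)),
              gehan_wilcoxon = n_j,
              tarone_ware = sqrt(n_j))
  U <- sum(w * (d_aj - n_aj * d_j / n_j))
  vterm <- ifelse(n_j <= 1, 0,
                  w^2 * (n_aj / n_j) * (1 - n_aj / n_j) *
                    ((n_j - d_j) / (n_j - 1)) * d_j)
  V <- sum(vterm)
  if (V <= 0) {
    return(structure(list(statistic = 0, p_value = 1,
                          weight_scheme = weight_scheme, degenerate = TRUE),
                     class = "surv_test"))
  }
  stat <- U^2 / V
  structure(list(statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 weight_scheme = weight_scheme, degenerate = FALSE),
            class = "surv_test")
}

#' @export
print.surv_test <- function(x, ...) {
  cat(sprintf("%s two-sample test: statistic = %.4g, p = %.4g%s\n",
              x$weight_scheme, x$statistic, x$p_value,
              if (x$degenerate) " (degenerate: zero variance)" else ""))
  invisible(x)
}
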