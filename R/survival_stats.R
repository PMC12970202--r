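#' Construct a survival cohort
#'
#' Per-subject right-censored survival records. Subjects alive at the end of
#' the study are censored at the end day for curve estimation and counted as
#' survivors for the cure-rate summary.
#'
#' @param records data.frame with columns `subject_id`, `group`,
#'   `time_days` (> 0) and `event` (1 = death, 0 = censored).
#' @return An object of class `survival_cohort`.
#' @export
survival_cohort <- function(records) {
  need <- c("subject_id", "group", "time_days", "event")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop("`records` must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(records$subject_id)) stop("duplicate subject_id")
  if (any(!is.finite(records$time_days)) || any(records$time_days <= 0)) {
    stop("times must be positive and finite")
  }
  if (!all(records$event %in% c(0, 1))) stop("event must be 0 or 1")
  records$group <- as.character(records$group)
  structure(list(records = records[need]), class = "survival_cohort")
}

#' Read a survival cohort from CSV
#'
#' @param path CSV with header `subject_id,group,time_days,event`.
#' @return A [survival_cohort()].
#' @export
read_cohort <- function(path) {
  survival_cohort(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Kaplan-Meier summary for one group
#'
#' Product-limit estimator (via [survival::survfit()]): at each distinct
#' event time `t`, `S <- S * (1 - d_t / n_t)` with `d_t` events among the
#' `n_t` subjects still at risk; censored subjects leave the risk set after
#' their time.
#'
#' @param cohort a [survival_cohort()].
#' @param group group label.
#' @param end_of_study_day day defining "alive at end of study" for the
#'   cure-rate summary; defaults to the largest observed time in the group.
#' @return An object of class `survival_summary`: `group`, `km_times`,
#'   `km_survival` (step values after each time), `median_days` (smallest
#'   `t` with `S(t) <= 0.5`, `NA` when the curve never reaches 0.5 —
#'   a cured-majority group), `n`, `survivors_at_end`, `cure_rate_pct`
#'   (integer-rounded).
#' @export
km_estimate <- function(cohort, group, end_of_study_day = NULL) {
  stopifnot(inherits(cohort, "survival_cohort"))
  rec <- cohort$records[cohort$records$group == group, , drop = FALSE]
  if (nrow(rec) == 0L) stop("group '", group, "' is empty")
  if (is.null(end_of_study_day)) end_of_study_day <- max(rec$time_days)
  fit <- survival::survfit(
    survival::Surv(time_days, event) ~ 1, data = rec, conf.type = "none")
  surv_at <- fit$surv
  med <- {
    i <- which(surv_at <= 0.5)
    if (length(i)) fit$time[min(i)] else NA_real_
  }
  survivors <- sum(rec$event == 0 & rec$time_days >= end_of_study_day)
  structure(list(group = group, km_times = fit$time, km_survival = surv_at,
                 median_days = med, n = nrow(rec),
                 survivors_at_end = survivors,
                 cure_rate_pct = cure_rate(survivors, nrow(rec))),
            class = "survival_summary")
}

#' @export
print.survival_summary <- function(x, ...) {
  cat(sprintf("<survival_summary> group '%s': n = %d, median = %s d, cure rate = %d%%\n",
              x$group, x$n,
              if (is.na(x$median_days)) "not reached" else format(x$median_days),
              x$cure_rate_pct))
  invisible(x)
}

#' Median survival from a Kaplan-Meier summary
#'
#' The smallest time `t` with `S(t) <= 0.5`; `NA` (undefined) when the curve
#' never reaches 0.5, as in groups where most subjects are cured.
#'
#' @param summary a `survival_summary`.
#' @return Median survival in days, or `NA`.
#' @export
median_survival <- function(summary) {
  stopifnot(inherits(summary, "survival_summary"))
  summary$median_days
}

# round-half-up to integer, the convention used for reported percentages
.round_half_up <- function(x) floor(x + 0.5)

#' Percent increase in median survival
#'
#' `100 * (treated - control) / control`, reported rounded up to the next
#' whole percent (ceiling). Published survival-increase figures round the
#' gain upward (a 36.4% gain is reported as 37%, a 33.6% gain as 34%); this
#' function reproduces that convention exactly from the printed medians.
#' Negative changes round toward zero.
#'
#' @param treated_median,control_median medians in days; `control_median > 0`.
#' @return Integer percent.
#' @export
percent_median_increase <- function(treated_median, control_median) {
  if (is.na(treated_median) || is.na(control_median)) {
    stop("undefined median input")
  }
  if (control_median <= 0) stop("`control_median` must be > 0")
  pct <- 100 * (treated_median - control_median) / control_median
  as.integer(ceiling(round(pct, 9)))
}

#' Cure rate as an integer percentage
#'
#' `round(100 * survivors / n)` with round-half-up.
#'
#' @param survivors subjects alive (tumor-free) at end of study.
#' @param n group size.
#' @return Integer percent.
#' @export
cure_rate <- function(survivors, n) {
  if (n <= 0) stop("`n` must be > 0")
  if (survivors < 0 || survivors > n) stop("need 0 <= survivors <= n")
  as.integer(.round_half_up(100 * survivors / n))
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic (via [survival::survdiff()]):
#' `chi2 = (O - E)^2 / V` summed over event times, with p from a chi-square
#' distribution on 1 degree of freedom. When the two groups combined have no
#' events the statistic is undefined and `NA` is returned with a note.
#'
#' @param cohort a [survival_cohort()].
#' @param group_a,group_b group labels.
#' @return List with `chi2`, `p`, and `note` (`NA` unless undefined).
#' @export
logrank_test <- function(cohort, group_a, group_b) {
  stopifnot(inherits(cohort, "survival_cohort"))
  rec <- cohort$records[cohort$records$group %in% c(group_a, group_b), ,
                        drop = FALSE]
  if (!any(rec$group == group_a)) stop("group '", group_a, "' is empty")
  if (!any(rec$group == group_b)) stop("group '", group_b, "' is empty")
  if (sum(rec$event) == 0) {
    return(list(chi2 = NA_real_, p = NA_real_,
                note = "no events in either group: log-rank undefined"))
  }
  sd <- survival::survdiff(survival::Surv(time_days, event) ~ group,
                           data = rec)
  chi2 <- as.numeric(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       note = NA_character_)
}

#' Holm step-down multiplicity adjustment (Bonferroni or Sidak flavor)
#'
#' Orders the m p-values increasingly and adjusts the i-th smallest by the
#' remaining number of hypotheses `m - i + 1`: Bonferroni multiplies,
#' Sidak applies `1 - (1 - p)^(m - i + 1)`. Running maxima enforce
#' monotonicity and results are clipped at 1.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @param method `"bonferroni"` (Holm-Bonferroni) or `"sidak"` (Holm-Sidak).
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(pvalues, method = c("bonferroni", "sidak")) {
  method <- match.arg(method)
  p <- as.numeric(pvalues)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric())
  o <- order(p)
  mult <- m - seq_len(m) + 1L
  adj_sorted <- switch(method,
                       bonferroni = p[o] * mult,
                       sidak = 1 - (1 - p[o])^mult)
  adj_sorted <- pmin(cummax(adj_sorted), 1)
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F test): F is the
#' between-group mean square over the within-group mean square, with p from
#' the F distribution. The degenerate case of zero within-group variance
#' with equal group means returns `F = 0, p = 1`.
#'
#' @param groups list of >= 2 numeric vectors, each of length >= 2.
#' @return List with `F`, `p`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  if (any(vapply(groups, length, integer(1L)) < 2L)) {
    stop("each group needs n >= 2")
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1L))))
  k <- length(groups); n <- length(y)
  within_var <- sum(vapply(groups, function(v) sum((v - mean(v))^2),
                           numeric(1L)))
  means <- vapply(groups, mean, numeric(1L))
  if (within_var == 0 && max(means) == min(means)) {
    return(list(F = 0, p = 1, df_between = k - 1L, df_within = n - k))
  }
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = as.numeric(ft$statistic), p = as.numeric(ft$p.value),
       df_between = k - 1L, df_within = n - k)
}
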