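#' Severity-by-outcome 2x2 tables
#'
#' Cross-tabulates each criterion's severity class against an outcome.
#' Records the missing-data rule excluded (`disposition ==
#' "excluded_borderline"`) are removed before counting and reported in the
#' `excluded` column, so `tp + fn + fp + tn + excluded` equals the cohort
#' size for every criterion.
#'
#' @param scores Output of [score_cohort()].
#' @param cohort The cohort the scores came from; must carry `died_6wk` and
#'   `icu_6wk` outcome columns matching `scores$patient_id` exactly.
#' @param outcome `"death"` (died within 6 weeks) or `"death_or_icu"`
#'   (death and/or ICU admission within 6 weeks).
#' @return A tibble with one row per criterion: `criterion`, `outcome`,
#'   `tp`, `fn`, `fp`, `tn`, `excluded`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 95, seed = 7))
#' scores <- score_cohort(cohort)
#' build_confusion_table(scores, cohort, outcome = "death")
#' @export
build_confusion_table <- function(scores, cohort,
                                  outcome = c("death", "death_or_icu")) {
  outcome <- match.arg(outcome)
  check_cohort_columns(cohort, outcomes = TRUE)
  extra <- setdiff(unique(scores$patient_id), cohort$patient_id)
  miss <- setdiff(cohort$patient_id, unique(scores$patient_id))
  if (length(extra) + length(miss) > 0) {
    abort(paste0(
      "Patient sets differ between scores and cohort. ",
      if (length(extra)) paste0("Scored but not in cohort: ",
                                paste(head(extra, 5), collapse = ", "), ". "),
      if (length(miss)) paste0("In cohort but unscored: ",
                               paste(head(miss, 5), collapse = ", "), ".")
    ))
  }
  ev <- tibble::tibble(
    patient_id = cohort$patient_id,
    event = if (outcome == "death") cohort$died_6wk == 1L
            else cohort$died_6wk == 1L | cohort$icu_6wk == 1L
  )
  scores |>
    dplyr::left_join(ev, by = "patient_id") |>
    dplyr::group_by(.data$criterion, .drop = FALSE) |>
    dplyr::summarise(
      outcome = outcome,
      tp = sum(.data$severity == "severe" & .data$event),
      fn = sum(.data$severity == "non_severe" & .data$event),
      fp = sum(.data$severity == "severe" & !.data$event),
      tn = sum(.data$severity == "non_severe" & !.data$event),
      excluded = sum(.data$severity == "excluded"),
      .groups = "drop"
    )
}

#' Build a 2x2 table from aggregate counts
#'
#' Reconstructs the severity-by-outcome cross-tabulation from the four
#' aggregate counts usually reported in papers: cohort size, number of
#' events, number classed severe, and number of events among the severe.
#'
#' @param criterion,outcome Labels carried through to the output.
#' @param n Number of analysed patients (after exclusions).
#' @param events Number with the outcome among the analysed.
#' @param severe Number classed severe.
#' @param severe_events Number classed severe who had the outcome.
#' @param excluded Records dropped by the missing-data rule (default 0).
#' @return One-row tibble in the [build_confusion_table()] shape.
#' @examples
#' confusion_from_counts("CURB65", "death",
#'                       n = 95, events = 8, severe = 28, severe_events = 7)
#' @export
confusion_from_counts <- function(criterion, outcome, n, events, severe,
                                  severe_events, excluded = 0L) {
  stopifnot(severe_events <= severe, severe_events <= events,
            events <= n, severe <= n)
  tibble::tibble(
    criterion = criterion, outcome = outcome,
    tp = as.integer(severe_events),
    fn = as.integer(events - severe_events),
    fp = as.integer(severe - severe_events),
    tn = as.integer(n - events - (severe - severe_events)),
    excluded = as.integer(excluded)
  )
}

#' Diagnostic accuracy metrics with confidence intervals
#'
#' Computes sensitivity, specificity, positive and negative predictive
#' value from 2x2 tables, each with a binomial confidence interval. The
#' default interval is the continuity-corrected Wilson score interval,
#' which matches the intervals printed in the audit literature this package
#' reproduces; the plain Wilson and Clopper-Pearson intervals are available
#' for sensitivity analysis.
#'
#' A metric whose denominator is zero (e.g. sensitivity with no events) is
#' reported as `NA`, never as 0.
#'
#' @param tables A tibble of 2x2 tables as produced by
#'   [build_confusion_table()] or [confusion_from_counts()].
#' @param ci_method `"wilson_cc"` (default), `"wilson"`, or
#'   `"clopper_pearson"`.
#' @param conf_level Confidence level, default 0.95.
#' @return A tibble with one row per (criterion, outcome, metric):
#'   `numerator`, `denominator`, `estimate`, `conf.low`, `conf.high`
#'   (proportions in \[0, 1\]).
#' @examples
#' tab <- confusion_from_counts("CURB65", "death", 95, 8, 28, 7)
#' accuracy_metrics(tab)
#' @export
accuracy_metrics <- function(tables,
                             ci_method = c("wilson_cc", "wilson", "clopper_pearson"),
                             conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  long <- purrr::pmap(
    tables[c("criterion", "outcome", "tp", "fn", "fp", "tn")],
    function(criterion, outcome, tp, fn, fp, tn) {
      tibble::tibble(
        criterion = criterion, outcome = outcome,
        metric = c("sensitivity", "specificity", "ppv", "npv"),
        numerator = c(tp, tn, tp, tn),
        denominator = c(tp + fn, tn + fp, tp + fp, tn + fn)
      )
    }
  ) |>
    purrr::list_rbind() |>
    dplyr::mutate(
      metric = factor(.data$metric,
                      levels = c("sensitivity", "specificity", "ppv", "npv")),
      estimate = ifelse(.data$denominator > 0,
                        .data$numerator / .data$denominator, NA_real_)
    )
  ci <- binomial_ci(long$numerator, long$denominator,
                    method = ci_method, conf_level = conf_level)
  long$conf.low <- ci$lower
  long$conf.high <- ci$upper
  long
}

#' Continuity-corrected Wilson interval for a binomial proportion
#'
#' The Wilson score interval with continuity correction (Newcombe's
#' method 4): the set of proportions not rejected by a continuity-corrected
#' score test. Bounds are clipped to \[0, 1\]; the lower bound is exactly 0
#' when `successes == 0` and the upper exactly 1 when `successes == n`.
#'
#' @param successes Number of successes (vectorised).
#' @param n Number of trials (>= 1).
#' @param conf_level Confidence level, default 0.95.
#' @return A tibble with columns `lower` and `upper`.
#' @examples
#' wilson_cc_interval(7, 8)    # reproduces the printed 46.7-99.3 interval
#' @export
wilson_cc_interval <- function(successes, n, conf_level = 0.95) {
  if (any(n < 1)) abort("`n` must be at least 1")
  if (any(successes < 0 | successes > n)) {
    abort("`successes` must lie in [0, n]")
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- successes / n
  lo <- (2 * n * p + z^2 - 1 -
           z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) /
    (2 * (n + z^2))
  hi <- (2 * n * p + z^2 + 1 +
           z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) /
    (2 * (n + z^2))
  lo <- ifelse(successes == 0, 0, pmax(0, lo))
  hi <- ifelse(successes == n, 1, pmin(1, hi))
  tibble::tibble(lower = lo, upper = hi)
}

binomial_ci <- function(successes, n, method, conf_level = 0.95) {
  ok <- n > 0
  out <- tibble::tibble(lower = rep(NA_real_, length(successes)),
                        upper = NA_real_)
  s <- successes[ok]; m <- n[ok]
  res <- switch(method,
    wilson_cc = wilson_cc_interval(s, m, conf_level),
    wilson = {
      z <- qnorm(1 - (1 - conf_level) / 2)
      p <- s / m
      centre <- (p + z^2 / (2 * m)) / (1 + z^2 / m)
      half <- z * sqrt(p * (1 - p) / m + z^2 / (4 * m^2)) / (1 + z^2 / m)
      tibble::tibble(lower = pmax(0, centre - half),
                     upper = pmin(1, centre + half))
    },
    clopper_pearson = {
      alpha <- 1 - conf_level
      tibble::tibble(
        lower = ifelse(s == 0, 0, qbeta(alpha / 2, s, m - s + 1)),
        upper = ifelse(s == m, 1, qbeta(1 - alpha / 2, s + 1, m - s))
      )
    }
  )
  out$lower[ok] <- res$lower
  out$upper[ok] <- res$upper
  out
}

#' Evaluate severity criteria on a cohort
#'
#' The full diagnostic-accuracy pipeline: scores the cohort, builds the
#' severity-by-outcome tables (applying the missing-data bounds rule), and
#' computes all four accuracy metrics with confidence intervals for every
#' requested criterion and outcome.
#'
#' @inheritParams score_cohort
#' @inheritParams accuracy_metrics
#' @param outcomes Outcomes to evaluate, a subset of
#'   `c("death", "death_or_icu")`.
#' @return A `cap_evaluation` object: a list with `metrics` (the
#'   [accuracy_metrics()] tibble), `tables` (the 2x2 counts), `scores`,
#'   and the call parameters. Use [tidy()] for the metric tibble,
#'   [glance()] for a one-row cohort summary, and [autoplot()] for a
#'   forest-style plot.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 95, seed = 11))
#' ev <- evaluate_criteria(cohort, criteria = c("CURB65", "CURSI"))
#' tidy(ev)
#' glance(ev)
#' @export
evaluate_criteria <- function(cohort,
                              criteria = cap_criterion_names(),
                              outcomes = c("death", "death_or_icu"),
                              asi_mode = c("continuous", "whole_degree"),
                              ci_method = c("wilson_cc", "wilson", "clopper_pearson"),
                              conf_level = 0.95) {
  if (nrow(cohort) == 0) abort("Cohort is empty")
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  asi_mode <- match.arg(asi_mode)
  ci_method <- match.arg(ci_method)
  scores <- score_cohort(cohort, criteria = criteria, asi_mode = asi_mode)
  tables <- purrr::map(outcomes,
                       \(o) build_confusion_table(scores, cohort, outcome = o)) |>
    purrr::list_rbind()
  metrics <- accuracy_metrics(tables, ci_method = ci_method,
                              conf_level = conf_level)
  structure(
    list(metrics = metrics, tables = tables, scores = scores,
         n = nrow(cohort), outcomes = outcomes, asi_mode = asi_mode,
         ci_method = ci_method, conf_level = conf_level),
    class = "cap_evaluation"
  )
}

#' @export
print.cap_evaluation <- function(x, ...) {
  cat("<cap_evaluation> ", x$n, " patients; criteria: ",
      paste(levels(x$tables$criterion), collapse = ", "),
      "; outcomes: ", paste(x$outcomes, collapse = ", "),
      "; CI: ", x$ci_method, "\n", sep = "")
  print(format_metric_table(x$metrics))
  invisible(x)
}

#' @rdname evaluate_criteria
#' @param x A `cap_evaluation` object.
#' @param ... Unused.
#' @export
tidy.cap_evaluation <- function(x, ...) x$metrics

#' @rdname evaluate_criteria
#' @export
glance.cap_evaluation <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_criteria = length(unique(x$tables$criterion)),
    n_outcomes = length(x$outcomes),
    total_excluded = sum(x$tables$excluded),
    ci_method = x$ci_method,
    conf_level = x$conf_level
  )
}

#' @rdname evaluate_criteria
#' @param object A `cap_evaluation` object.
#' @export
autoplot.cap_evaluation <- function(object, ...) {
  ggplot2::ggplot(
    object$metrics,
    ggplot2::aes(x = .data$estimate, y = .data$criterion,
                 xmin = .data$conf.low, xmax = .data$conf.high)
  ) +
    ggplot2::geom_pointrange() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$outcome),
                        cols = ggplot2::vars(.data$metric)) +
    ggplot2::scale_x_continuous(labels = \(p) paste0(100 * p, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "estimate (95% CI)", y = NULL)
}
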