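#' Wilcoxon signed-rank test for paired classifications
#'
#' Paired signed-rank test with an exact null distribution (full
#' enumeration of sign assignments, computed by convolution) whenever the
#' number of non-zero differences is at most `exact_limit`, and a normal
#' approximation with tie correction above it. Absolute differences are
#' ranked with midranks for ties.
#'
#' Zero differences are handled by the classical `"drop"` convention
#' (discarded before ranking) or by Pratt's method (`"pratt"`: zeros enter
#' the ranking but contribute to neither sign). When every difference is
#' zero the test carries no information: the p-value is reported as 1 with
#' `degenerate = TRUE`.
#'
#' @param x,y Paired numeric vectors of equal length (typically per-patient
#'   0/1 severity classifications under two criteria).
#' @param zero_policy `"drop"` (default) or `"pratt"`.
#' @param exact_limit Largest number of non-zero differences for which the
#'   exact distribution is enumerated (default 25).
#' @return One-row tibble: `statistic` (V, the sum of ranks of positive
#'   differences), `p_value` (two-sided), `n_pairs`, `n_nonzero`, `method`,
#'   `degenerate`.
#' @examples
#' wilcoxon_signed_rank(c(1, 1, 1, 1, 0), c(0, 0, 0, 0, 0))
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 zero_policy = c("drop", "pratt"),
                                 exact_limit = 25) {
  zero_policy <- match.arg(zero_policy)
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  if (length(d) < 1) abort("Need at least one pair")
  if (anyNA(d)) abort("Differences contain NA")
  n_pairs <- length(d)
  nz <- d != 0
  n_nonzero <- sum(nz)

  if (n_nonzero == 0) {
    return(tibble::tibble(statistic = 0, p_value = 1, n_pairs = n_pairs,
                          n_nonzero = 0L, method = "degenerate",
                          degenerate = TRUE))
  }

  if (zero_policy == "drop") {
    dd <- d[nz]
    r <- rank(abs(dd))
  } else {
    r_all <- rank(abs(d))  # zeros share the lowest midranks
    dd <- d[nz]
    r <- r_all[nz]
  }
  v <- sum(r[dd > 0])

  if (n_nonzero <= exact_limit) {
    # exact: distribution of V over all 2^m sign assignments, by convolution
    # over doubled ranks (midranks are half-integers)
    r2 <- as.integer(round(2 * r))
    dist <- signrank_distribution(r2)
    v2 <- as.integer(round(2 * v))
    p_le <- sum(dist$prob[dist$value <= v2])
    p_ge <- sum(dist$prob[dist$value >= v2])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)  # tie-robust: Var(V) = sum(r_i^2)/4
    z <- (v - mu) / sigma
    p <- 2 * pnorm(-abs(z))
    method <- "normal_approximation"
  }
  tibble::tibble(statistic = v, p_value = p, n_pairs = n_pairs,
                 n_nonzero = as.integer(n_nonzero), method = method,
                 degenerate = FALSE)
}

# Null distribution of sum of a random subset of `weights` (each included
# independently with probability 1/2), as value/probability pairs.
signrank_distribution <- function(weights) {
  total <- sum(weights)
  counts <- numeric(total + 1)  # counts[s + 1] = #assignments with sum s
  counts[1] <- 1
  for (w in weights) {
    shifted <- c(rep(0, w), counts[seq_len(total + 1 - w)])
    counts <- counts + shifted
  }
  tibble::tibble(value = 0:total, prob = counts / 2^length(weights)) |>
    dplyr::filter(.data$prob > 0)
}

#' Exact McNemar test for paired binary classifications
#'
#' Companion to [wilcoxon_signed_rank()] for strictly binary paired
#' classifications: an exact binomial test on the discordant pairs
#' (patients classified severe by one criterion only).
#'
#' @inheritParams wilcoxon_signed_rank
#' @return One-row tibble: `b` (x = 1, y = 0 pairs), `c` (x = 0, y = 1
#'   pairs), `p_value` (exact two-sided), `degenerate` (no discordant
#'   pairs).
#' @examples
#' mcnemar_exact(c(1, 1, 1, 1, 1), c(0, 0, 0, 0, 0))  # p = 2 * 0.5^5
#' @export
mcnemar_exact <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (!all(c(x, y) %in% c(0, 1))) abort("Entries must be 0/1")
  b <- sum(x == 1 & y == 0)
  cc <- sum(x == 0 & y == 1)
  if (b + cc == 0) {
    warn("No discordant pairs; McNemar test is degenerate")
    return(tibble::tibble(b = b, c = cc, p_value = 1, degenerate = TRUE))
  }
  p <- stats::binom.test(b, b + cc, p = 0.5)$p.value
  tibble::tibble(b = b, c = cc, p_value = min(1, p), degenerate = FALSE)
}

#' Compare two criteria's classifications on the same cohort
#'
#' Pairs the per-patient binary severity classifications of two criteria
#' within a subgroup — patients with the outcome for sensitivity
#' comparisons, patients without it for specificity comparisons — and runs
#' a paired test. Patients excluded by the missing-data rule under either
#' criterion are left out of the pairing.
#'
#' @inheritParams evaluate_criteria
#' @param pair Character vector of two criterion names.
#' @param outcome `"death"` or `"death_or_icu"`.
#' @param subgroup `"events"` (sensitivity comparison) or `"non_events"`
#'   (specificity comparison).
#' @param test `"wilcoxon"` (signed-rank, default) or `"mcnemar"`.
#' @param zero_policy Passed to [wilcoxon_signed_rank()].
#' @return One-row tibble: `criterion_a`, `criterion_b`, `outcome`,
#'   `subgroup`, `n`, `statistic`, `p_value`, `method`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 95, seed = 3))
#' compare_criteria(cohort, pair = c("CURSI", "CURB65"), outcome = "death",
#'                  subgroup = "events")
#' @export
compare_criteria <- function(cohort, pair, outcome = c("death", "death_or_icu"),
                             subgroup = c("events", "non_events"),
                             asi_mode = c("continuous", "whole_degree"),
                             test = c("wilcoxon", "mcnemar"),
                             zero_policy = c("drop", "pratt")) {
  outcome <- match.arg(outcome)
  subgroup <- match.arg(subgroup)
  test <- match.arg(test)
  pair <- match_criteria(pair)
  if (length(pair) != 2) abort("`pair` must name exactly two criteria")
  scores <- score_cohort(cohort, criteria = pair, asi_mode = asi_mode)
  event <- if (outcome == "death") cohort$died_6wk == 1L
           else cohort$died_6wk == 1L | cohort$icu_6wk == 1L
  keep_ids <- cohort$patient_id[if (subgroup == "events") event else !event]

  wide <- scores |>
    dplyr::filter(.data$patient_id %in% keep_ids,
                  .data$severity != "excluded") |>
    dplyr::mutate(severe = as.integer(.data$severity == "severe")) |>
    dplyr::select("patient_id", "criterion", "severe") |>
    tidyr::pivot_wider(names_from = "criterion", values_from = "severe") |>
    tidyr::drop_na()
  if (nrow(wide) == 0) abort("Subgroup is empty after exclusions")

  a <- wide[[pair[1]]]; b <- wide[[pair[2]]]
  res <- if (test == "wilcoxon") {
    wilcoxon_signed_rank(a, b, zero_policy = zero_policy)
  } else {
    r <- mcnemar_exact(a, b)
    tibble::tibble(statistic = r$b, p_value = r$p_value,
                   method = "mcnemar_exact", degenerate = r$degenerate)
  }
  tibble::tibble(
    criterion_a = pair[1], criterion_b = pair[2],
    outcome = outcome, subgroup = subgroup, n = nrow(wide),
    statistic = res$statistic, p_value = res$p_value, method = res$method,
    degenerate = res$degenerate
  )
}
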