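#' Component flags for every record
#'
#' Evaluates each severity-score component on every record of a cohort.
#' Flags are record-level: the same flags feed every criterion that uses the
#' component. A flag is 1 when the component's cutoff is met, 0 when it is
#' not, and `NA` (indeterminate) when the underlying measurement is missing.
#'
#' Cutoff semantics are exactly as the criteria are written: urea > 7 mmol/L
#' and shock indices > 1.0 are strict, respiratory rate >= 30/min and
#' age >= 65 are not, low blood pressure is systolic < 90 mmHg *or*
#' diastolic <= 60 mmHg for a single point.
#'
#' @param cohort A data frame with the cohort columns (see [read_cohort()]).
#' @param asi_mode Temperature-adjustment mode for the adjusted shock index,
#'   passed to [adjusted_shock_index()].
#' @return A tibble with `patient_id` and integer columns `C`, `U`, `R`,
#'   `B`, `65`, `SI`, `ASI` in `{0, 1, NA}`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 5, seed = 1))
#' component_flags(cohort)
#' @export
component_flags <- function(cohort, asi_mode = c("continuous", "whole_degree")) {
  asi_mode <- match.arg(asi_mode)
  check_cohort_columns(cohort)
  si <- shock_index(cohort$heart_rate, cohort$sbp)
  asi <- adjusted_shock_index(cohort$heart_rate, cohort$sbp,
                              cohort$temperature, mode = asi_mode)
  tibble::tibble(
    patient_id = cohort$patient_id,
    C = as.integer(cohort$confusion),
    U = as.integer(cohort$urea > 7.0),
    R = as.integer(cohort$resp_rate >= 30),
    B = as.integer(cohort$sbp < 90 | cohort$dbp <= 60),
    `65` = as.integer(cohort$age >= 65),
    SI = as.integer(si > 1.0),
    ASI = as.integer(asi > 1.0)
  )
}

#' Score a cohort against severity criteria
#'
#' Applies one or more severity criteria to every record, with a
#' deterministic bounds rule for missing components: each record gets a
#' `score_lower` (missing components counted as 0) and a `score_upper`
#' (missing components counted as 1). A record is classed
#' `severe` when `score_lower` already reaches the criterion's cutoff,
#' `non_severe` when even `score_upper` stays below it, and `excluded`
#' when the two bounds straddle the cutoff — the only case in which a
#' missing value could change the severity class. This reproduces the
#' allocate-despite-missing / exclude-borderline handling used in audit
#' practice: patients whose recorded values already pin down the class are
#' kept in their group irrespective of the absent value.
#'
#' @inheritParams component_flags
#' @param criteria Character vector of criterion names (see
#'   [cap_criteria()]); case and punctuation insensitive.
#' @return A tibble with one row per (patient, criterion): the record-level
#'   component flags, `score_lower`, `score_upper`, `severity`
#'   (`severe`/`non_severe`/`excluded`) and `disposition` (`complete`,
#'   `allocated_despite_missing`, `excluded_borderline`).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 20, seed = 42))
#' score_cohort(cohort, criteria = c("CURB65", "CURSI"))
#' @export
score_cohort <- function(cohort, criteria = cap_criterion_names(),
                         asi_mode = c("continuous", "whole_degree")) {
  asi_mode <- match.arg(asi_mode)
  criteria <- match_criteria(criteria)
  flags <- component_flags(cohort, asi_mode = asi_mode)
  defs <- dplyr::filter(cap_criteria(), .data$criterion %in% criteria)

  purrr::pmap(defs, function(criterion, components, severe_cutoff, max_score) {
    fl <- as.matrix(flags[, components, drop = FALSE])
    lower <- as.integer(rowSums(fl, na.rm = TRUE))
    n_miss <- as.integer(rowSums(is.na(fl)))
    upper <- lower + n_miss
    severity <- dplyr::case_when(
      lower >= severe_cutoff ~ "severe",
      upper < severe_cutoff ~ "non_severe",
      TRUE ~ "excluded"
    )
    disposition <- dplyr::case_when(
      n_miss == 0L ~ "complete",
      severity == "excluded" ~ "excluded_borderline",
      TRUE ~ "allocated_despite_missing"
    )
    tibble::tibble(
      patient_id = flags$patient_id,
      criterion = criterion,
      flags[, components, drop = FALSE] |> tibble::as_tibble(),
      score_lower = lower,
      score_upper = upper,
      severity = severity,
      disposition = disposition
    )
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(criterion = factor(.data$criterion, levels = criteria))
}

cohort_columns <- c(
  "patient_id", "age", "sex", "confusion", "urea", "resp_rate",
  "sbp", "dbp", "heart_rate", "temperature"
)

check_cohort_columns <- function(cohort, outcomes = FALSE) {
  need <- cohort_columns
  if (outcomes) need <- c(need, "died_6wk", "icu_6wk")
  missing <- setdiff(need, names(cohort))
  if (length(missing) > 0) {
    abort(paste0("Cohort is missing columns: ", paste(missing, collapse = ", ")))
  }
  invisible(cohort)
}
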