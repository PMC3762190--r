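#' Read a cohort CSV
#'
#' Reads a per-admission cohort table: comma-separated, UTF-8, header row
#' required, one record per admission, missing values as an empty field or
#' `NA`. Required columns:
#' `patient_id`, `age` (years), `sex` (`male`/`female`), `confusion`
#' (0/1, may be missing), `urea` (mmol/L, may be missing), `resp_rate`
#' (breaths/min), `sbp`/`dbp` (mmHg), `heart_rate` (beats/min),
#' `temperature` (degrees C), `died_6wk`, `icu_6wk` (0/1).
#'
#' Records are validated against plausibility bounds (age 0-120,
#' temperature 25-45 degrees C, heart rate 20-250, respiratory rate 4-80,
#' systolic BP 40-300 mmHg, urea 0-60 mmol/L) and the systolic > diastolic
#' invariant. Violations are load errors reported with line numbers — they
#' are never silently clamped.
#'
#' @param path Path to the CSV file.
#' @return A validated cohort tibble.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_cohort(generate_cohort(cohort_spec(n = 5, seed = 2)), path)
#' read_cohort(path)
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  cohort <- readr::read_csv(
    path, na = c("", "NA"), show_col_types = FALSE,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      sex = readr::col_character(),
      confusion = readr::col_integer(),
      resp_rate = readr::col_integer(),
      died_6wk = readr::col_integer(),
      icu_6wk = readr::col_integer(),
      .default = readr::col_double()
    )
  )
  unknown <- setdiff(names(cohort), c(cohort_columns, "died_6wk", "icu_6wk"))
  if (length(unknown) > 0) {
    abort(paste0("Unknown columns: ", paste(unknown, collapse = ", ")))
  }
  validate_cohort(cohort)
}

#' Validate a cohort table
#'
#' Applies the schema and plausibility checks described in
#' [read_cohort()] to an in-memory data frame. All offending rows are
#' collected and reported together (data line numbers count the header as
#' line 1).
#'
#' @param cohort A data frame.
#' @return The cohort as a tibble, invisibly validated.
#' @export
validate_cohort <- function(cohort) {
  check_cohort_columns(cohort, outcomes = TRUE)
  cohort <- tibble::as_tibble(cohort)
  problems <- character()
  flag <- function(bad, what) {
    idx <- which(!is.na(bad) & bad)
    if (length(idx) > 0) {
      problems <<- c(problems, paste0(
        "line ", paste(idx + 1L, collapse = ", "), ": ", what))
    }
  }
  flag(is.na(cohort$age) | cohort$age < 0 | cohort$age > 120,
       "age outside 0-120")
  flag(!cohort$sex %in% c("male", "female"), "sex not male/female")
  flag(!is.na(cohort$confusion) & !cohort$confusion %in% c(0L, 1L),
       "confusion not 0/1/missing")
  flag(!is.na(cohort$urea) & (cohort$urea <= 0 | cohort$urea > 60),
       "urea outside (0, 60]")
  flag(is.na(cohort$resp_rate) | cohort$resp_rate < 4 | cohort$resp_rate > 80,
       "resp_rate outside 4-80")
  flag(is.na(cohort$sbp) | cohort$sbp < 40 | cohort$sbp > 300,
       "sbp outside 40-300")
  flag(is.na(cohort$dbp) | cohort$dbp <= 0, "dbp missing or non-positive")
  flag(cohort$sbp <= cohort$dbp, "sbp not greater than dbp")
  flag(is.na(cohort$heart_rate) | cohort$heart_rate < 20 | cohort$heart_rate > 250,
       "heart_rate outside 20-250")
  flag(is.na(cohort$temperature) | cohort$temperature < 25 | cohort$temperature > 45,
       "temperature outside 25-45")
  flag(!cohort$died_6wk %in% c(0L, 1L), "died_6wk not 0/1")
  flag(!cohort$icu_6wk %in% c(0L, 1L), "icu_6wk not 0/1")
  if (anyDuplicated(cohort$patient_id)) {
    problems <- c(problems, "duplicate patient_id values")
  }
  if (length(problems) > 0) {
    abort(paste0("Cohort validation failed:\n  ",
                 paste(problems, collapse = "\n  ")))
  }
  cohort
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: writes the cohort in the same CSV dialect
#' (missing values as empty fields) so a write-read round trip is the
#' identity up to floating-point formatting.
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}
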