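#' Published audit-cohort counts
#'
#' The severity-by-outcome counts reported for the 95-patient inpatient
#' audit cohort on which the six criteria were originally compared, as
#' aggregate counts: analysed patients, events, patients classed severe,
#' and events among the severe. Two analysis sets are represented: the
#' urea-based criteria (CURB-65, CURSI, CURASI) were evaluated on 95
#' patients with 8 deaths and 11 death-or-ICU events; the urea-free
#' criteria (CRB-65, CRSI, CRASI) on 95 patients (one different patient
#' excluded) with 8 deaths and 12 composite events.
#'
#' The published report is internally inconsistent for one cell: the
#' CRB-65 mortality table implies 4 deaths among the 11 patients classed
#' severe (sensitivity 50% of 8), while the accompanying narrative counts
#' 3 deaths plus a fourth patient admitted to ICU. `crb65_death_path`
#' selects which arithmetic path to reproduce; the default `"table"`
#' (4 deaths) is the one consistent with every printed metric.
#'
#' @param crb65_death_path `"table"` (default) or `"narrative"`.
#' @return A tibble with columns `criterion`, `outcome`, `n`, `events`,
#'   `severe`, `severe_events`.
#' @seealso [study_tables()] for the corresponding 2x2 tables.
#' @examples
#' study_counts()
#' @export
study_counts <- function(crb65_death_path = c("table", "narrative")) {
  crb65_death_path <- match.arg(crb65_death_path)
  crb65_d <- if (crb65_death_path == "table") 4L else 3L
  tibble::tribble(
    ~criterion, ~outcome,        ~n, ~events, ~severe, ~severe_events,
    "CURB65",   "death",         95L, 8L,     28L,     7L,
    "CURSI",    "death",         95L, 8L,     31L,     7L,
    "CURASI",   "death",         95L, 8L,     31L,     7L,
    "CURB65",   "death_or_icu",  95L, 11L,    28L,     8L,
    "CURSI",    "death_or_icu",  95L, 11L,    31L,     9L,
    "CURASI",   "death_or_icu",  95L, 11L,    31L,     9L,
    "CRB65",    "death",         95L, 8L,     11L,     crb65_d,
    "CRSI",     "death",         95L, 8L,     20L,     6L,
    "CRASI",    "death",         95L, 8L,     19L,     6L,
    "CRB65",    "death_or_icu",  95L, 12L,    11L,     4L,
    "CRSI",     "death_or_icu",  95L, 12L,    20L,     7L,
    "CRASI",    "death_or_icu",  95L, 12L,    19L,     7L
  )
}

#' Published audit-cohort 2x2 tables
#'
#' Expands [study_counts()] into the twelve severity-by-outcome 2x2
#' tables (six criteria by two outcomes), ready for [accuracy_metrics()].
#'
#' @inheritParams study_counts
#' @return A tibble in the [build_confusion_table()] shape.
#' @examples
#' study_tables() |> accuracy_metrics()
#' @export
study_tables <- function(crb65_death_path = c("table", "narrative")) {
  purrr::pmap(study_counts(crb65_death_path), confusion_from_counts) |>
    purrr::list_rbind()
}
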