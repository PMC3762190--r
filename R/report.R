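#' Format accuracy metrics as a criteria-by-metrics table
#'
#' Reshapes the long [accuracy_metrics()] tibble into the layout used in
#' the clinical literature: one block per outcome, metrics as rows,
#' criteria as columns, each cell `"est% (lo-hi)"`. Percentages are
#' rounded to one decimal place, half away from zero.
#'
#' @param metrics An [accuracy_metrics()] tibble.
#' @return A tibble with columns `outcome`, `metric`, and one column per
#'   criterion.
#' @examples
#' format_metric_table(accuracy_metrics(study_tables()))
#' @export
format_metric_table <- function(metrics) {
  metrics |>
    dplyr::mutate(cell = ifelse(
      is.na(.data$estimate), "--",
      paste0(fmt_pct(.data$estimate), "% (",
             fmt_pct(.data$conf.low), "-", fmt_pct(.data$conf.high), ")")
    )) |>
    dplyr::select("outcome", "metric", "criterion", "cell") |>
    tidyr::pivot_wider(names_from = "criterion", values_from = "cell")
}

# one decimal place, half away from zero (sprintf/round use half-to-even)
fmt_pct <- function(p) {
  x <- 100 * p
  formatC(sign(x) * floor(abs(x) * 10 + 0.5) / 10, format = "f", digits = 1)
}

#' Render an evaluation report to files
#'
#' Writes a deterministic set of plain-text report files for an
#' evaluation: the accuracy table per outcome (TSV and aligned text in the
#' `"est% (lo-hi)"` layout), the severity-by-outcome breakdown counts, a
#' per-criterion ledger of patients excluded by the missing-data rule, and
#' optionally a paired-comparison table. Progress is logged with
#' `message()`: cohort size, exclusions per criterion, CI method.
#'
#' @param evaluation A [evaluate_criteria()] result.
#' @param comparisons Optional tibble of [compare_criteria()] rows; when
#'   `NULL` or empty the comparison section is omitted and a log line says
#'   so.
#' @param dir Output directory (created if needed).
#' @param basename Stem for output file names.
#' @return Character vector of the files written, invisibly.
#' @examples
#' ev <- evaluate_criteria(generate_cohort(cohort_spec(n = 95, seed = 5)))
#' render_report(ev, dir = tempfile())
#' @export
render_report <- function(evaluation, comparisons = NULL, dir = ".",
                          basename = "cap_report") {
  stopifnot(inherits(evaluation, "cap_evaluation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, basename)
  written <- character()

  message("cohort: ", evaluation$n, " patients; CI method: ",
          evaluation$ci_method)

  wide <- format_metric_table(evaluation$metrics)
  f <- paste0(stem, "_metrics.tsv")
  readr::write_tsv(wide, f)
  written <- c(written, f)

  txt <- character()
  for (oc in unique(wide$outcome)) {
    block <- wide |>
      dplyr::filter(.data$outcome == oc) |>
      dplyr::select(-"outcome")
    txt <- c(txt, paste0("Outcome: ", oc), aligned_text(block), "")
  }
  f <- paste0(stem, "_metrics.txt")
  writeLines(txt, f)
  written <- c(written, f)

  breakdown <- evaluation$tables |>
    dplyr::mutate(
      analysed = .data$tp + .data$fn + .data$fp + .data$tn,
      severe = .data$tp + .data$fp,
      events = .data$tp + .data$fn,
      severe_events = .data$tp
    ) |>
    dplyr::select("criterion", "outcome", "analysed", "severe", "events",
                  "severe_events", "excluded")
  f <- paste0(stem, "_breakdown.tsv")
  readr::write_tsv(breakdown, f)
  written <- c(written, f)

  ledger <- evaluation$scores |>
    dplyr::mutate(status = ifelse(.data$severity == "excluded",
                                  "excluded", "analysed")) |>
    dplyr::select("patient_id", "criterion", "status", "disposition")
  f <- paste0(stem, "_ledger.tsv")
  readr::write_tsv(ledger, f)
  written <- c(written, f)
  excl <- dplyr::filter(ledger, .data$status == "excluded")
  for (cr in unique(evaluation$scores$criterion)) {
    message("criterion ", cr, ": ",
            sum(excl$criterion == cr), " patient(s) excluded")
  }

  if (!is.null(comparisons) && nrow(comparisons) > 0) {
    f <- paste0(stem, "_comparisons.tsv")
    readr::write_tsv(comparisons, f)
    written <- c(written, f)
  } else {
    message("no comparisons supplied; comparison section omitted")
  }
  invisible(written)
}

aligned_text <- function(df) {
  cols <- vapply(names(df), function(nm) {
    vals <- c(nm, as.character(df[[nm]]))
    formatC(vals, width = max(nchar(vals)), flag = "-")
  }, character(nrow(df) + 1))
  apply(cols, 1, paste, collapse = "  ")
}
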