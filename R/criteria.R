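#' The six severity criteria
#'
#' Returns the definitions of the six CAP severity criteria handled by the
#' package. Each criterion is a sum of one-point components; a patient whose
#' total reaches `severe_cutoff` is classed as severe pneumonia.
#'
#' The components are:
#' \describe{
#'   \item{C}{new mental confusion}
#'   \item{U}{blood urea > 7 mmol/L (strict)}
#'   \item{R}{respiratory rate >= 30 /min}
#'   \item{B}{systolic BP < 90 mmHg or diastolic BP <= 60 mmHg (one point)}
#'   \item{65}{age >= 65 years}
#'   \item{SI}{shock index (heart rate / systolic BP) > 1.0 (strict)}
#'   \item{ASI}{temperature-adjusted shock index > 1.0 (strict)}
#' }
#'
#' CURB-65 and CRB-65 are classed severe at 3 or more points; the
#' shock-index criteria (CURSI, CURASI, CRSI, CRASI) at 2 or more.
#'
#' @return A tibble with one row per criterion: `criterion`, `components`
#'   (list-column of component codes), `severe_cutoff`, `max_score`.
#' @examples
#' cap_criteria()
#' @export
cap_criteria <- function() {
  tibble::tibble(
    criterion = c("CURB65", "CRB65", "CURSI", "CURASI", "CRSI", "CRASI"),
    components = list(
      c("C", "U", "R", "B", "65"),
      c("C", "R", "B", "65"),
      c("C", "U", "R", "SI"),
      c("C", "U", "R", "ASI"),
      c("C", "R", "SI"),
      c("C", "R", "ASI")
    ),
    severe_cutoff = c(3L, 3L, 2L, 2L, 2L, 2L),
    max_score = c(5L, 4L, 4L, 4L, 3L, 3L)
  )
}

#' @rdname cap_criteria
#' @export
cap_criterion_names <- function() cap_criteria()$criterion

match_criteria <- function(criteria) {
  known <- cap_criterion_names()
  criteria <- toupper(gsub("[-_ ]", "", criteria))
  criteria[criteria == "CURB"] <- "CURB65"
  bad <- setdiff(criteria, known)
  if (length(bad) > 0) {
    abort(paste0(
      "Unknown criteria: ", paste(bad, collapse = ", "),
      ". Available: ", paste(known, collapse = ", ")
    ))
  }
  criteria
}

#' Shock index
#'
#' The shock index is the ratio of heart rate (beats/min) to systolic blood
#' pressure (mmHg); a ratio above 1.0 contributes one point to the SI-based
#' severity criteria.
#'
#' @param heart_rate Heart rate in beats/min (positive).
#' @param sbp Systolic blood pressure in mmHg (positive).
#' @return Numeric vector of dimensionless ratios. `NA` inputs give `NA`.
#' @examples
#' shock_index(110, 95)
#' @export
shock_index <- function(heart_rate, sbp) {
  check_positive(heart_rate, "heart_rate")
  check_positive(sbp, "sbp")
  heart_rate / sbp
}

#' Temperature-adjusted shock index
#'
#' Recomputes the shock index after deducting 10 beats/min from the heart
#' rate for every 1.0 degree C of body temperature above 37.0 degrees C,
#' discounting the physiological tachycardia of fever. Temperatures at or
#' below 37.0 never raise the heart rate, and the adjusted heart rate is
#' floored at zero so the ratio stays defined.
#'
#' @inheritParams shock_index
#' @param temperature Body temperature in degrees Celsius.
#' @param mode `"continuous"` (default) deducts `10 * (temperature - 37)`
#'   for any fractional excess; `"whole_degree"` deducts 10 per *completed*
#'   degree above 37.0.
#' @return Numeric vector of dimensionless ratios.
#' @examples
#' adjusted_shock_index(110, 100, 38.0)           # (110 - 10) / 100 = 1
#' adjusted_shock_index(101, 100, 37.5)           # continuous: 0.96
#' adjusted_shock_index(101, 100, 37.5, mode = "whole_degree")  # 1.01
#' @export
adjusted_shock_index <- function(heart_rate, sbp, temperature,
                                 mode = c("continuous", "whole_degree")) {
  mode <- match.arg(mode)
  check_positive(heart_rate, "heart_rate")
  check_positive(sbp, "sbp")
  excess <- pmax(0, temperature - 37.0)
  if (mode == "whole_degree") excess <- floor(excess)
  pmax(0, heart_rate - 10 * excess) / sbp
}

check_positive <- function(x, name) {
  if (any(!is.na(x) & x <= 0)) {
    abort(paste0("`", name, "` must be strictly positive"))
  }
  invisible(x)
}
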