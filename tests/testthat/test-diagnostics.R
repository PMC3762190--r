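test_that("confusion tables count severity against outcome, minus exclusions", {
  cohort <- dplyr::bind_rows(
    make_record("s1", confusion = 1L, urea = 9, resp_rate = 34L, age = 70,
                died_6wk = 1L),                               # severe, died
    make_record("s2", confusion = 1L, urea = 9, resp_rate = 34L, age = 70),
    make_record("n1", died_6wk = 1L),                         # mild, died
    make_record("n2"),
    make_record("n3", icu_6wk = 1L),                          # mild, ICU only
    make_record("x1", confusion = NA_integer_, urea = 9, resp_rate = 34L)
  )  # x1: CURB-65 lower 2 / upper 3 -> excluded
  scores <- score_cohort(cohort, criteria = "CURB65")
  tab <- build_confusion_table(scores, cohort, outcome = "death")
  expect_equal(tab[c("tp", "fn", "fp", "tn", "excluded")],
               tibble::tibble(tp = 1L, fn = 1L, fp = 1L, tn = 2L,
                              excluded = 1L),
               ignore_attr = TRUE)
  comp <- build_confusion_table(scores, cohort, outcome = "death_or_icu")
  expect_equal(comp$fn, 2)   # the ICU-only patient becomes an event
  # partition invariant
  expect_equal(tab$tp + tab$fn + tab$fp + tab$tn + tab$excluded, nrow(cohort))
})

test_that("empty input yields an all-zero table", {
  cohort <- make_record()[0, ]
  tab <- build_confusion_table(score_cohort(cohort, criteria = "CURB65"),
                               cohort, outcome = "death")
  expect_equal(nrow(tab), 1)
  expect_true(all(tab[c("tp", "fn", "fp", "tn", "excluded")] == 0))
})

test_that("mismatched patient sets are reported by id", {
  cohort <- dplyr::bind_rows(make_record("a"), make_record("b"))
  scores <- score_cohort(cohort, criteria = "CURB65")
  expect_error(build_confusion_table(scores, cohort[1, ], "death"), "b")
})

test_that("counts reconstruction matches the published severe/event arithmetic", {
  tab <- confusion_from_counts("CURB65", "death", n = 95, events = 8,
                               severe = 28, severe_events = 7)
  expect_equal(tab[c("tp", "fn", "fp", "tn")],
               tibble::tibble(tp = 7L, fn = 1L, fp = 21L, tn = 66L),
               ignore_attr = TRUE)
  tab <- confusion_from_counts("CURSI", "death_or_icu", n = 95, events = 11,
                               severe = 31, severe_events = 9)
  expect_equal(tab[c("tp", "fn", "fp", "tn")],
               tibble::tibble(tp = 9L, fn = 2L, fp = 22L, tn = 62L),
               ignore_attr = TRUE)
})

test_that("accuracy metrics are the four standard 2x2 proportions", {
  m <- accuracy_metrics(confusion_from_counts("CURB65", "death", 95, 8, 28, 7))
  est <- setNames(m$estimate, as.character(m$metric))
  expect_equal(est, c(sensitivity = 7 / 8, specificity = 66 / 87,
                      ppv = 7 / 28, npv = 66 / 67))
  m <- accuracy_metrics(confusion_from_counts("CRSI", "death", 95, 8, 20, 6))
  est <- setNames(m$estimate, as.character(m$metric))
  expect_equal(est, c(sensitivity = 0.75, specificity = 73 / 87,
                      ppv = 0.3, npv = 73 / 75))
})

test_that("zero denominators give undefined metrics, not zero", {
  tab <- tibble::tibble(criterion = "CURB65", outcome = "death",
                        tp = 0L, fn = 0L, fp = 5L, tn = 5L, excluded = 0L)
  m <- accuracy_metrics(tab)
  expect_true(is.na(m$estimate[m$metric == "sensitivity"]))
  expect_false(anyNA(m$estimate[m$metric != "sensitivity"]))
})

test_that("Wilson CC interval reproduces known bounds and clips at 0/1", {
  expect_equal(round(unlist(wilson_cc_interval(7, 8)), 3),
               c(lower = 0.467, upper = 0.993))
  expect_equal(round(unlist(wilson_cc_interval(4, 8)), 3),
               c(lower = 0.174, upper = 0.826))
  expect_identical(wilson_cc_interval(0, 10)$lower, 0)
  expect_identical(wilson_cc_interval(10, 10)$upper, 1)
  expect_error(wilson_cc_interval(3, 0), "at least 1")
  expect_error(wilson_cc_interval(5, 3), "successes")
})

test_that("Wilson CC closed form agrees with the score-equation root to 1e-9", {
  for (n in 1:50) {
    s <- 0:n
    got <- wilson_cc_interval(s, n)
    want <- t(vapply(s, wilson_cc_brute, numeric(2), n = n))
    expect_equal(got$lower, want[, "lower"], tolerance = 1e-9)
    expect_equal(got$upper, want[, "upper"], tolerance = 1e-9)
  }
})

test_that("Wilson CC interval contains the estimate and narrows with n", {
  for (k in c(1, 3, 7)) {
    n <- c(8, 16, 40, 80, 200)
    ci <- wilson_cc_interval(k * n / 8, n)
    expect_true(all(ci$lower <= k / 8 & k / 8 <= ci$upper))
    widths <- ci$upper - ci$lower
    expect_true(all(diff(widths) < 0))
  }
})

test_that("relabelling both classes swaps sensitivity/specificity and ppv/npv", {
  tab <- confusion_from_counts("A", "death", 60, 13, 20, 9)
  swapped <- tibble::tibble(criterion = "A", outcome = "death",
                            tp = tab$tn, fn = tab$fp, fp = tab$fn,
                            tn = tab$tp, excluded = 0L)
  m1 <- accuracy_metrics(tab)
  m2 <- accuracy_metrics(swapped)
  get <- function(m, what) m$estimate[m$metric == what]
  expect_equal(get(m2, "sensitivity"), get(m1, "specificity"))
  expect_equal(get(m2, "specificity"), get(m1, "sensitivity"))
  expect_equal(get(m2, "ppv"), get(m1, "npv"))
  expect_equal(get(m2, "npv"), get(m1, "ppv"))
})

test_that("alternative CI methods bracket sensibly", {
  cc <- wilson_cc_interval(7, 8)
  plain <- capscore:::binomial_ci(7, 8, "wilson")
  cp <- capscore:::binomial_ci(7, 8, "clopper_pearson")
  expect_true(plain$lower > cc$lower && plain$upper < cc$upper)
  expect_true(cp$lower < plain$lower)   # Clopper-Pearson is conservative
  # Clopper-Pearson cross-check against binom.test
  bt <- binom.test(7, 8)$conf.int
  expect_equal(unlist(cp), c(lower = bt[1], upper = bt[2]),
               tolerance = 1e-12)
})

test_that("a perfect classifier evaluates to unit sensitivity and specificity", {
  cohort <- dplyr::bind_rows(
    purrr::map(1:4, \(i) make_record(paste0("s", i), confusion = 1L, urea = 9,
                                     resp_rate = 34L, age = 70, died_6wk = 1L)),
    purrr::map(1:6, \(i) make_record(paste0("n", i)))
  )
  ev <- evaluate_criteria(cohort, criteria = "CURB65", outcomes = "death")
  est <- setNames(tidy(ev)$estimate, as.character(tidy(ev)$metric))
  expect_equal(unname(est), c(1, 1, 1, 1))
  expect_equal(glance(ev)$total_excluded, 0L)
})

test_that("a one-patient cohort defines only the occupied cells", {
  ev <- evaluate_criteria(make_record(died_6wk = 1L), criteria = "CURB65",
                          outcomes = "death")
  m <- tidy(ev)
  expect_equal(m$estimate[m$metric == "sensitivity"], 0)  # classed non-severe
  expect_true(is.na(m$estimate[m$metric == "specificity"]))
  expect_true(is.na(m$estimate[m$metric == "ppv"]))
  expect_equal(m$estimate[m$metric == "npv"], 0)
})

test_that("autoplot returns a ggplot of the metric grid", {
  ev <- evaluate_criteria(generate_cohort(cohort_spec(n = 60, seed = 13)),
                          criteria = c("CURB65", "CURSI"))
  expect_s3_class(autoplot(ev), "ggplot")
})
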