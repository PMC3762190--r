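test_that("shock index is the heart-rate / systolic ratio", {
  expect_equal(shock_index(100, 100), 1.0)
  expect_equal(shock_index(120, 80), 1.5)
  expect_equal(shock_index(56, 208), 56 / 208)
  expect_error(shock_index(0, 100), "positive")
  expect_error(shock_index(100, -5), "positive")
})

test_that("adjusted shock index deducts 10 bpm per degree above 37", {
  expect_equal(adjusted_shock_index(110, 100, 38.0), 1.0)
  expect_equal(adjusted_shock_index(100, 100, 36.0), 1.0)  # never increases
  expect_equal(adjusted_shock_index(101, 100, 37.5), 0.96)
  expect_equal(adjusted_shock_index(101, 100, 37.5, mode = "whole_degree"), 1.01)
  # adjusted heart rate is floored at zero
  expect_equal(adjusted_shock_index(20, 100, 40.0), 0)
})

test_that("adjusted index never exceeds the raw index and matches it below 37", {
  set.seed(42)
  hr <- runif(200, 40, 180); sbp <- runif(200, 70, 210)
  temp <- runif(200, 33, 41)
  for (mode in c("continuous", "whole_degree")) {
    asi <- adjusted_shock_index(hr, sbp, temp, mode = mode)
    expect_true(all(asi <= shock_index(hr, sbp) + 1e-12))
    cold <- temp <= 37
    expect_equal(asi[cold], shock_index(hr, sbp)[cold])
  }
})

test_that("component cutoffs follow the written boundary semantics", {
  rec <- dplyr::bind_rows(
    make_record("a", urea = 7.0),                    # strict >
    make_record("b", urea = 7.0001),
    make_record("c", resp_rate = 30L),               # >= 30
    make_record("d", age = 65),                      # >= 65
    make_record("e", heart_rate = 100, sbp = 100, dbp = 65),   # SI exactly 1
    make_record("f", sbp = 90, dbp = 61),            # sbp strict < 90
    make_record("g", sbp = 89.9, dbp = 61),
    make_record("h", dbp = 60)                       # dbp <= 60
  )
  fl <- component_flags(rec)
  expect_equal(fl$U[1:2], c(0L, 1L))
  expect_equal(fl$R[3], 1L)
  expect_equal(fl$`65`[4], 1L)
  expect_equal(fl$SI[5], 0L)
  expect_equal(fl$B[6:8], c(0L, 1L, 1L))
})

test_that("a record at the cohort medians scores zero on CURB-65", {
  rec <- make_record(age = 61, confusion = 0L, urea = 6.65, resp_rate = 24L,
                     sbp = 130, dbp = 74)
  fl <- component_flags(rec)
  expect_equal(unlist(fl[1, c("C", "U", "R", "B", "65")]),
               c(C = 0L, U = 0L, R = 0L, B = 0L, `65` = 0L))
})

test_that("missing measurements propagate to indeterminate flags, not errors", {
  rec <- make_record(confusion = NA_integer_, urea = NA_real_)
  fl <- component_flags(rec)
  expect_true(is.na(fl$C) && is.na(fl$U))
  expect_equal(fl$R, 0L)
})

test_that("scoring classes severity by the bounds rule", {
  # every CURB-65 component met
  all5 <- make_record(confusion = 1L, urea = 8, resp_rate = 32L,
                      sbp = 85, dbp = 55, age = 70)
  s <- score_cohort(all5, criteria = "CURB65")
  expect_equal(s$score_lower, 5L)
  expect_equal(s$severity, "severe")
  expect_equal(s$disposition, "complete")

  # borderline CRB-65: missing confusion with R=1, B=1, 65=0 straddles the cutoff
  border <- make_record(confusion = NA_integer_, resp_rate = 32L,
                        sbp = 85, dbp = 55, age = 50)
  s <- score_cohort(border, criteria = "CRB65")
  expect_equal(s$score_lower, 2L)
  expect_equal(s$score_upper, 3L)
  expect_equal(s$severity, "excluded")
  expect_equal(s$disposition, "excluded_borderline")

  # missing urea but already at the CURB-65 cutoff: allocated severe anyway
  pinned <- make_record(confusion = 1L, urea = NA_real_, resp_rate = 32L,
                        sbp = 130, dbp = 80, age = 70)
  s <- score_cohort(pinned, criteria = "CURB65")
  expect_equal(s$score_lower, 3L)
  expect_equal(s$severity, "severe")
  expect_equal(s$disposition, "allocated_despite_missing")
})

test_that("complete records have equal score bounds and complete disposition", {
  spec <- cohort_spec(n = 120, seed = 5,
                      missing = list(urea = 0, confusion = 0))
  scores <- score_cohort(generate_cohort(spec))
  expect_true(all(scores$score_lower == scores$score_upper))
  expect_true(all(scores$disposition == "complete"))
  expect_true(all(scores$severity %in% c("severe", "non_severe")))
})

test_that("worsening any vital never lowers a criterion score", {
  set.seed(7)
  base <- generate_cohort(cohort_spec(n = 50, seed = 8,
                                      missing = list(urea = 0, confusion = 0)))
  lower0 <- score_cohort(base)$score_lower
  worse <- base |>
    dplyr::mutate(confusion = 1L, urea = urea + 5, resp_rate = resp_rate + 8L,
                  heart_rate = heart_rate + 30,
                  dbp = pmin(dbp, sbp - 60 - 1), sbp = sbp - 60)
  expect_true(all(score_cohort(worse)$score_lower >= lower0))
})

test_that("severity over all 32 flag patterns matches a brute-force scorer", {
  grid <- expand.grid(C = 0:1, U = 0:1, R = 0:1, B = 0:1, A65 = 0:1)
  cohort <- purrr::pmap(grid, function(C, U, R, B, A65) {
    make_record(
      patient_id = paste0("p", C, U, R, B, A65),
      confusion = C, urea = if (U) 9 else 5,
      resp_rate = if (R) 34L else 18L,
      sbp = if (B) 85 else 140, dbp = if (B) 55 else 80,
      age = if (A65) 70 else 40
    )
  }) |> purrr::list_rbind()
  got <- score_cohort(cohort, criteria = "CURB65")
  expected <- ifelse(rowSums(grid) >= 3, "severe", "non_severe")
  expect_equal(got$severity, expected)
  expect_equal(got$score_lower, as.integer(rowSums(grid)))
})

test_that("fever-adjusted criteria equal their raw forms at or below 37 degrees", {
  cohort <- generate_cohort(cohort_spec(n = 150, seed = 21)) |>
    dplyr::mutate(temperature = pmin(temperature, 37))
  for (mode in c("continuous", "whole_degree")) {
    s <- score_cohort(cohort, criteria = c("CURSI", "CURASI", "CRSI", "CRASI"),
                      asi_mode = mode)
    w <- tidyr::pivot_wider(
      s[c("patient_id", "criterion", "score_lower", "score_upper")],
      names_from = "criterion",
      values_from = c("score_lower", "score_upper"))
    expect_equal(w$score_lower_CURASI, w$score_lower_CURSI)
    expect_equal(w$score_lower_CRASI, w$score_lower_CRSI)
    expect_equal(w$score_upper_CURASI, w$score_upper_CURSI)
  }
})
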