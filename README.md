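# capscore

Severity scoring and diagnostic accuracy for community-acquired pneumonia
(CAP) criteria, in R.

When a patient is admitted with pneumonia, clinicians need a fast, reliable
estimate of how ill they are. The standard bedside rule is **CURB-65** — one
point each for **C**onfusion, **U**rea > 7 mmol/L, **R**espiratory rate
≥ 30/min, low **B**lood pressure (systolic < 90 or diastolic ≤ 60 mmHg) and
age ≥ **65**; a score of 3+ is "severe". Because chronological age can
mislead in both directions, age-independent variants replace the age and
blood-pressure items with the **shock index** SI = HR/SBP (one point when
SI > 1.0), optionally **temperature-adjusted** (ASI: deduct 10 bpm from the
heart rate per 1.0 °C above 37.0 °C before taking the ratio, discounting
fever tachycardia). That yields **CURSI**/**CURASI** and, dropping urea for
primary-care use, **CRSI**/**CRASI** (all severe at 2+), alongside
**CRB-65** (severe at 3+).

`capscore` implements all six criteria and the full machinery needed to
evaluate and compare them on a per-patient vital-sign table:

* **Scoring with a deterministic missing-data bounds rule.** Each record
  gets a score interval: `score_lower` counts definite points,
  `score_upper` additionally counts indeterminate (missing) components. A
  patient is excluded only when the interval straddles the severity
  cutoff — exactly the allocate-despite-missing / exclude-borderline
  handling used in clinical audit practice.
* **Diagnostic accuracy.** 2×2 severity-by-outcome tables (6-week death,
  or death and/or ICU admission), with sensitivity, specificity, PPV and
  NPV and 95% **continuity-corrected Wilson** confidence intervals
  (plain Wilson and Clopper–Pearson available for sensitivity analysis).
* **Paired comparison.** Exact Wilcoxon signed-rank (full enumeration up
  to 25 non-zero differences, tie-corrected normal approximation above)
  and exact McNemar tests on per-patient paired classifications.
* **A seedable synthetic cohort generator** whose truncated marginal
  distributions are numerically moment-matched to a published 95-patient
  respiratory-admissions audit cohort, with a latent-severity outcome
  model calibrated to its event rates — so the entire pipeline runs and is
  testable without any patient data.
* **Reporting**: TSV/plain-text tables in the familiar
  `estimate% (lo–hi)` journal layout, severity-outcome breakdowns and an
  exclusion ledger, plus a thin command-line tool
  (`inst/exec/capscore`) with `simulate`, `score`, `evaluate` and
  `compare` subcommands.

Everything is data-frame-in / tibble-out and pipe-friendly; evaluation
results support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Reproduce the published accuracy tables of the audit cohort the six
criteria were compared on. The published report gives aggregate counts (95
analysed patients; 8 deaths; 11 or 12 composite events; per-criterion
severe and severe-event counts), which `study_counts()` ships and
`study_tables()` expands into 2×2 tables:

```r
library(capscore)

study_tables() |>
  accuracy_metrics(ci_method = "wilson_cc") |>
  format_metric_table()
```

```
  outcome      metric      CURB65            CURSI             CURASI
1 death        sensitivity 87.5% (46.7-99.3) 87.5% (46.7-99.3) 87.5% (46.7-99.3)
2 death        specificity 75.9% (65.3-84.1) 72.4% (61.6-81.2) 72.4% (61.6-81.2)
3 death        ppv         25.0% (11.4-45.2) 22.6% (10.3-41.5) 22.6% (10.3-41.5)
4 death        npv         98.5% (90.9-99.9) 98.4% (90.5-99.9) 98.4% (90.5-99.9)
5 death_or_icu sensitivity 72.7% (39.3-92.7) 81.8% (47.8-96.8) 81.8% (47.8-96.8)
...
```

Read: of the 8 patients who died, CURB-65 had classed 7 as severe
(sensitivity 87.5%, 95% CI 46.7–99.3); of the 87 survivors it had classed
66 as non-severe (specificity 75.9%). For the composite death-or-ICU
outcome the shock-index criteria are more sensitive than CURB-65 (81.8%
vs 72.7%) at slightly lower specificity — the clinical argument for an
age-independent rule in younger cohorts.

The same pipeline runs on any cohort CSV (or a simulated one):

```r
cohort <- generate_cohort(cohort_spec(n = 95, seed = 1))   # or read_cohort("cohort.csv")
ev <- evaluate_criteria(cohort, criteria = c("CURB65", "CURSI", "CURASI"))
tidy(ev)          # long tibble: criterion x outcome x metric with CIs
autoplot(ev)      # forest-style metric grid
compare_criteria(cohort, pair = c("CURSI", "CURB65"),
                 outcome = "death", subgroup = "events")
render_report(ev, dir = "report")
```

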