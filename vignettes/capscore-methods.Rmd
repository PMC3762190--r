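---
title: "Methods: severity criteria, accuracy estimation and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: severity criteria, accuracy estimation and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capscore)
```

This vignette documents the models and procedures behind `capscore`, the
choices made where the design was genuinely open, and what the package's
tests do and do not establish.

## The six criteria

All six rules are unweighted sums of one-point components with a severity
cutoff:

| criterion | components | severe at |
|---|---|---|
| CURB-65 | C, U, R, B, 65 | ≥ 3 |
| CRB-65  | C, R, B, 65    | ≥ 3 |
| CURSI   | C, U, R, SI    | ≥ 2 |
| CURASI  | C, U, R, ASI   | ≥ 2 |
| CRSI    | C, R, SI       | ≥ 2 |
| CRASI   | C, R, ASI      | ≥ 2 |

Component cutoffs are implemented with exactly the strict/non-strict
boundaries the rules are stated with, and the boundaries are pinned by
tests: urea **> 7** mmol/L, respiratory rate **≥ 30**/min, systolic
**< 90** mmHg *or* diastolic **≤ 60** mmHg (a single point), age
**≥ 65**, shock index and adjusted shock index **> 1.0**. A patient with
urea exactly 7.0 or a shock index of exactly 1.0 scores no point; a
respiratory rate of exactly 30 does.

### The adjusted shock index

The adjustment deducts 10 beats/min from the heart rate per 1.0 °C of
temperature above 37.0 °C before taking the HR/SBP ratio. Two readings of
"per 1.0 °C increase" are defensible: a *continuous* deduction
(10 × (T − 37.0), so 38.6 °C deducts 16 bpm) or one per *completed whole
degree* (38.6 °C deducts 10 bpm). The package defaults to the continuous
reading — it is the smoother, assumption-minimal interpretation and does
not privilege arbitrary 1-degree bins — and exposes the whole-degree
variant through `asi_mode = "whole_degree"` on every scoring entry point.
Two further conventions close the definition: temperatures at or below
37.0 °C never *raise* the heart rate (the adjustment is defined as a
deduction, not a symmetric correction), and the adjusted heart rate is
floored at 0 so the ratio stays defined for extreme fever with low heart
rate. Below 37.0 °C the adjusted criteria coincide with their unadjusted
forms, a property the test suite checks in both modes.

## Missing data: the bounds rule

Audit practice handles missing score components case by case: a patient
whose recorded values already determine the severity class is kept in
that class; a patient whose class could flip with the missing value is
excluded. `capscore` generalises this narrative into a deterministic
rule. For each record and criterion it computes

* `score_lower` — indeterminate components scored 0, and
* `score_upper` — indeterminate components scored 1.

The class is `severe` when `score_lower` already reaches the cutoff,
`non_severe` when even `score_upper` falls short, and `excluded`
(disposition `excluded_borderline`) only when the bounds straddle the
cutoff. For complete records the bounds coincide and the disposition is
`complete`. The rule reproduces every allocation and exclusion described
in the audit narrative (a severe patient with one missing item and three
definite points stays severe; a borderline non-severe patient with
missing confusion is excluded), is order-independent, and needs no
imputation model. Excluded records are removed before the 2×2 tables are
built and accounted for in an explicit `excluded` column, so
`tp + fn + fp + tn + excluded` always equals the cohort size.

## Accuracy metrics and confidence intervals

Sensitivity, specificity, PPV and NPV are the usual 2×2 proportions; a
metric whose denominator is empty (e.g. sensitivity in a cohort with no
events) is reported `NA`, never 0.

The confidence intervals are **Wilson score intervals with continuity
correction** (Newcombe's method 4): the bounds solve

$$\left|\hat p - p\right| - \tfrac{1}{2n} = z \sqrt{p(1-p)/n},
\qquad z = \Phi^{-1}(0.975),$$

clipped to [0, 1], with the lower bound exactly 0 at $\hat p = 0$ and the
upper exactly 1 at $\hat p = 1$. This method was identified by
reverse-engineering the intervals printed in the audit literature the
package reproduces: it regenerates every printed interval to the printed
decimal (up to the tables' own truncation; e.g. the exact upper bound for
4/8 is 82.554%, printed as 82.5). The closed form is verified against a
numeric root of the defining score equation to 10⁻⁹ over every
$(s, n)$ with $n \le 50$. Plain Wilson and Clopper–Pearson intervals are
available behind `ci_method=` for sensitivity analysis; Clopper–Pearson
is cross-checked against `binom.test()`.

Display rounding is one decimal place, half away from zero. Published
tables round inconsistently (truncating in places), so numeric
comparisons in the tests use unrounded values with a ±0.1 percentage
point band, which absorbs those artefacts.

One published cell is internally inconsistent: the CRB-65 mortality
column implies 4 deaths among the 11 patients classed severe (50% of 8,
specificity 91.9%), while the accompanying severity-group narrative
counts 3 deaths plus one ICU admission. `study_counts()` defaults to the
table-consistent path (4) and exposes the narrative path through
`crb65_death_path = "narrative"`; the package reproduces both
arithmetics and does not attempt to adjudicate.

## Paired comparison of criteria

The source analysis compared criteria with a Wilcoxon signed-rank test
but does not state the pairing unit. The only paired structure available
from a single cohort is the per-patient binary classification, so
`compare_criteria()` pairs each patient's severe/non-severe indicator
under two criteria, restricted to the relevant subgroup — patients with
the outcome when comparing sensitivities, patients without it for
specificities — after dropping patients excluded under either criterion.
Because the data behind the published P values are unavailable, those P
values are not reproduction targets anywhere in the package.

`wilcoxon_signed_rank()` is built for this degenerate-heavy setting:
differences of paired 0/1 classifications are mostly zero with massive
ties. Zeros follow the classical drop convention by default (Pratt's
method behind `zero_policy = "pratt"`), absolute differences are ranked
with midranks, and the null distribution of the positive-rank sum is
computed *exactly* by convolution over doubled midranks whenever at most
25 non-zero differences remain (the two-sided p is twice the smaller
tail, capped at 1); beyond that a normal approximation with the
tie-robust variance $\sum r_i^2/4$ is used. The exact path is verified
against brute-force enumeration of all sign assignments for $n \le 10$
and against `stats::wilcox.test` on tie-free cases (R's exact path does
not handle ties, which is why the distribution is computed in-package).
When every difference is zero the test carries no information; p = 1 is
returned with a `degenerate` flag rather than an error. An exact McNemar
test (`mcnemar_exact()`, binomial tail on discordant pairs) is provided
as the natural companion for strictly binary paired classifiers.

## The synthetic cohort generator

`cohort_spec()` / `generate_cohort()` emulate the marginal structure of
the 95-patient inpatient audit cohort so that every pipeline stage can be
exercised, at any sample size, with no patient data.

**Marginals.** Age, respiratory rate, systolic and diastolic pressure,
heart rate and temperature are truncated normals on the observed ranges;
sex and confusion are Bernoulli (56.8%, 28.4%). Urea is a truncated
log-normal: its reported median (6.65) sits well below its mean (7.9),
the signature of a right-skewed lab value. In every case the underlying
parameters are *solved numerically so that the truncated distribution
matches the reported moments* (mean/sd, or median/mean for urea). Naive
truncation at the observed range would not do this — truncating a normal
with mean 58.8 and sd 18.75 to [17, 96] shifts the mean by about −0.4
years — and parameter recovery is a tested property (sample moments of a
10⁵-record cohort within 3 Monte-Carlo standard errors of the targets).
Respiratory rate is rounded to an integer; the added rounding variance
(1/12) is far inside the Monte-Carlo band.

**Systolic/diastolic ordering.** Diastolic pressure is drawn
conditionally below the same patient's systolic value (inverse-CDF
sampling from the per-record truncated range, which is distributionally
identical to resampling until the draw falls below systolic). The
constraint shifts the diastolic marginal, so its parameters are
calibrated against the *constrained* marginal by integrating the
per-systolic truncated moments over the systolic distribution.

**Outcome model.** Each patient carries a latent severity burden $z$ — a
fixed-weight standardised combination of confusion, log-urea,
respiratory rate, shock index and (weakly) age, i.e. the physiology the
criteria monitor — plus an independent standard-normal frailty $e$
shared by both outcomes. Death and ICU admission are Bernoulli with
logits $a_{d} + \beta z + \tau e$ and $a_{i} + \beta z + \tau e$
(defaults $\beta = 1.6$, $\tau = 2$). The intercepts are calibrated on
the cohort at hand: $a_d$ so that the expected death count is
$n \times 8/95$, and $a_i$ so that the expected death-or-ICU *composite*
count is $n \times 11.5/95$ (the audit reported 11 composite events in
one analysis set and 12 in the other). The composite, not the ICU
marginal, is the calibration target because it is the quantity the
evaluation uses. With $\beta = 0$ the model degenerates to
intercept-only rates (a tested property), and criterion sensitivity
rises monotonically with $\beta$ (tested over a slope grid).

**What the generator does not emulate.** Beyond the systolic/diastolic
ordering and the outcome model, variables are independent: the source
table reports only marginals, and no joint vital-sign correlation (e.g.
heart rate with temperature) is imposed. Consequently, passing tests on
synthetic cohorts demonstrate that the pipeline's *logic* is correct
under realistic marginals and calibrated event rates — they do not
certify criterion performance on real patients, where vitals co-vary and
missingness is informative rather than completely at random (the
generator's default MCAR rates are 1% for urea and confusion). No
attempt is made to reconstruct the actual 95 patients.

## Numerical and degenerate-input conventions

* All randomness flows through one seeded generator
  (`withr::with_seed`); the global RNG state is untouched. Identical
  seeds give byte-identical cohorts and reports.
* Moment-matching calibrations run Nelder–Mead to a relative tolerance
  of 10⁻¹⁴; logistic intercepts are solved by `uniroot` to 10⁻¹⁰ on
  [−40, 40].
* Plausibility bounds (age 0–120, temperature 25–45 °C, heart rate
  20–250, respiratory rate 4–80, systolic 40–300 mmHg, urea ≤ 60 mmol/L,
  systolic > diastolic) are *load errors* with line numbers, never
  silent clamps.
* Empty cohorts produce all-zero 2×2 tables; single-patient cohorts
  define only the occupied metrics; zero denominators give `NA`.
* Test problem sizes: property loops use cohorts of 50–200 records;
  distributional checks use 2 × 10⁴–10⁵ records and 120–200 replicate
  cohorts at n = 95, which keeps the full suite under ten seconds on one
  CPU while leaving Monte-Carlo bands comfortably tighter than the
  effects they check.

## Known limitations

* The inter-vital correlation structure is unmodelled (see above); a
  Gaussian-copula layer would be the natural extension.
* The signed-rank comparison inherits the ambiguity of its published
  use: with paired 0/1 data it is equivalent to a sign test on
  discordant pairs, and `mcnemar_exact()` is usually the better-posed
  choice.
* Medication effects on heart rate and blood pressure (e.g.
  beta-blockade) are outside the scoring rules and are not modelled.
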