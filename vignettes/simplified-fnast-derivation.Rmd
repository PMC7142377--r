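---
title: "Deriving a simplified 8-item neonatal abstinence score: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving a simplified 8-item neonatal abstinence score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnast8)
```

## The problem

Neonatal abstinence syndrome (NAS) — opioid withdrawal in newborns after
in-utero exposure — is assessed at the bedside with serial scores on the
Finnegan Neonatal Abstinence Scoring Tool (FNAST): 21 graded items, each
grade carrying an integer weight from 1 to 5, summed to a severity score.
Site protocols initiate pharmacologic treatment when consecutive scores
cross predetermined cutoffs (for example, 3 consecutive scores of at least
8, or 2 of at least 12).  The tool is long, several items are hard to grade
reproducibly, and raters differ.

`fnast8` implements, as a tested and reusable pipeline, the derivation of a
simplified scale from the full instrument:

1. **Dichotomization** — every graded item becomes a present/absent sign
   (any recorded grade counts as present), removing the weights.
2. **Analysis point** — one assessment per neonate: the highest-scoring
   assessment on the day treatment was first given, or on day 3 of life for
   never-treated neonates (day 3 is the median day of treatment initiation
   among treated neonates).
3. **Cross-cohort screening** — per-sign Pearson chi-square homogeneity
   tests across derivation cohorts, a concordance (AUC) comparison of
   endorsement across cohorts, and exclusion of signs that are never
   observed or whose cohort endorsement rates differ by more than 50
   percentage points.
4. **Selection** — forward stepwise logistic regression of treatment
   receipt on the surviving signs, adjusting for cohort (entry *P* < .10,
   retention *P* < .05), with model discrimination summarized by the AUC.
5. **Threshold calibration** — cutpoints for the new 0–8 score chosen to
   maximize linear-weighted Cohen's kappa against the original scale's
   fixed categories (< 8, 8–11, ≥ 12).
6. **External validation** — the selected signs refitted on an independent
   cohort and discrimination reported.

The patient-level data behind the published derivation were never
deposited.  Everything that *is* printed — the full item catalogue and its
weights, per-cohort endorsement counts of every dichotomized sign, the
grade-level frequencies, and the 3×3 category crosstab at the chosen
cutpoints — ships with the package as plain-text fixtures
(`reference_endorsement_counts()`, `reference_level_counts()`,
`reference_crosstab()`), and a calibrated synthetic-cohort generator stands
in for the raw data so that every downstream stage is exercised end to end.

## Statistical components

### Screening statistics

`chi2_homogeneity()` is the Pearson chi-square test on the 2×k table of
(endorsed, not endorsed) by cohort, **without** continuity correction and
without an exact-test fallback, df = k − 1.  This choice is itself checked
by the test suite: with the published counts it reproduces every printed
p-value at its printed rounding, including the small-cell nasal-flaring
item (cells of 4 and 5; printed *P* = .04).  An all-or-none sign takes the
degenerate path (statistic 0, *P* = 1).

The published cross-cohort "endorsement AUC" is not fully specified in
words; `endorsement_auc()` adopts the interpretation that reproduces both
published values: each neonate is scored by its *cohort's* endorsement rate
of the sign, and the concordance between endorsed and non-endorsed neonates
is computed with ties counted one-half.  With the published counts this
yields 0.79 for high-pitched crying and 0.72 for hyperactive Moro reflex —
the reproduction is part of the test suite, which also checks the midrank
computation against brute-force pair counting.  The confidence interval
uses the Hanley–McNeil asymptotic variance; the published intervals'
method is unstated (the Moro interval is asymmetric), so the CI is reported
but never used for decisions.

The heterogeneity filter excludes signs with `max_pp_difference()` strictly
greater than 50 percentage points, computed from counts, not from the
rounded printed percentages.  Never-observed signs are excluded separately;
a sign endorsed by *every* neonate is retained by the screen (exclusion has
only the two stated criteria) but flagged zero-variance and withheld from
the regression candidate set.

### Logistic regression and stepwise selection

`fit_logistic()` is a self-contained maximum-likelihood fit by iteratively
reweighted least squares.  Numerical choices: start at zero; step-halving
whenever a Newton step would decrease the log-likelihood (so the
log-likelihood is non-decreasing by construction); convergence when the
largest absolute score component falls below 1e-8 or the relative
log-likelihood change falls below 1e-10; at most 50 iterations.  Any
coefficient exceeding 15 on the logit scale flags probable separation: the
fit is returned (no crash) but marked non-converged and downstream Wald
p-values are suppressed.  An optional Firth penalized-score mode gives
finite estimates under separation; it is off by default, since the
published univariate odds ratio of 10.0 (CI 3.9–26.0) for increased muscle
tone suggests near-separation was tolerated in the original analysis.  The
suite cross-checks coefficients, covariance and log-likelihood against both
a brute-force optimizer and `glm()`.

`forward_stepwise()` forces cohort indicators into every model (reference =
largest cohort; item odds ratios are invariant to that choice) and
iterates: compute an entry p-value for every remaining candidate against
the current model, add the smallest if *P* < .10 (ties broken
lexicographically by sign id), then re-test all included signs by Wald p
and remove any with *P* ≥ .05, worst first, refitting after each removal.
The entry statistic is a likelihood-ratio test by default with a Rao score
test available (`entry_test = "score"`); the original analysis named no
statistic, and its software's historical default is the score test, so
neither is claimed as "the" truth.  Because entry and retention use
different statistics, a sign near both thresholds can cycle in and out;
the implementation stops on the first repeated selected-set state and logs
it in the trace.  Candidates whose augmented design is rank-deficient
(e.g. a duplicate column) are skipped with a trace entry.

The two tremor signs are distinct dichotomized signs but a single item on
the simplified scale.  The regression default is the single combined
`any_tremors` indicator (`tremor_mode = "any"`), matching the scale that is
ultimately scored; the two-indicator mode is a configuration switch.  The
published final model prints separate tremor odds ratios, so neither
parameterization is uniquely "correct"; this is recorded as an open choice,
not a fact.

### Threshold calibration

`weighted_kappa()` implements chance-corrected agreement with
Cicchetti–Allison linear weights `w_ij = 1 − |i−j|/(r−1)`.  Linear rather
than quadratic weights are a deliberate choice: linear weights reproduce
the published kappa of 0.55 from the published crosstab, quadratic weights
do not — the reproduction is a test.  The CI uses the large-sample
(Fleiss–Cohen–Everitt) variance; the published CI method is unstated.
`select_thresholds()` scans all 28 integer pairs `1 ≤ t1 < t2 ≤ 8` (t1 ≥ 1
so the low category is non-empty in principle; strict inequality so all
three categories exist), maximizing kappa with ties broken toward the
smallest pair; the suite asserts the result equals an independent
exhaustive rescan.  The original scale's cutpoints are fixed at (8, 12)
throughout — they were predetermined clinically, not fitted.

## The synthetic generator: what it emulates

`simulate_cohorts()` generates longitudinal multi-cohort assessment
streams with the statistical structure the analysis assumes:

* **Severity trajectory.** Each neonate has a latent withdrawal severity
  `S(t) = H · max(0, 1 − |t − P|/width)`: a unimodal trajectory peaking at
  day `P ~ N(3, 0.75²)` (mean at the published median day of treatment
  initiation) with height `H ~ N(0, 1.2²)`.  `H` is deliberately
  unbounded below: negative heights are milder-than-baseline neonates, and
  the spread of `H` is what separates treated from untreated trajectories.
* **Occasion noise.** Each assessment adds a shared `N(0, 0.69²)`
  occasion/rater effect to `S`.  This term is load-bearing: it lets single
  high scores occur without sustained runs, decoupling the max-of-day
  analysis marginals from the consecutive-score treatment triggers.
  Without it, cohorts with high published endorsement rates are driven
  almost entirely to treatment, which contradicts the published treated
  fraction.
* **Items.** Given `S`, each binary sign is endorsed independently with
  probability `plogis(offset[sign, cohort] + loading[sign] · S)`.
  Endorsed graded items escalate to higher grades by comparing `S` plus
  logistic noise against per-item thresholds.  Loadings are the stated
  world: 1.6 for the nine source signs of the simplified scale, 0.7 for
  the other observed signs, 0 for never-observed ones.
* **Treatment.** Treatment is score-rule-driven, not an independent label:
  a neonate is treated on the day its cohort's consecutive-score rule
  first triggers on its simulated score sequence (Kentucky sites 3×≥8 or
  2×≥12; multisite trial 2×≥8 or 1×≥12; validation cohort 2×≥9 or 1×≥13).
  The truth log records the trigger day, and the suite re-verifies every
  label against the rules on every run.
* **Calibration.** Per-cohort sign offsets, grade-escalation thresholds
  and the occasion-noise SD were moment-matched offline (fixed-point
  iteration, with bisection for the occasion SD, at 15× cohort sizes) so
  that analysis-point endorsement rates track the published per-cohort
  rates, conditional grade-level frequencies track the published level
  counts, and the overall derivation treated fraction tracks 238/424.
  The fitted values are frozen as package defaults; they are a stated
  world, not tuning knobs.

Features of real data the generator does **not** emulate, and which a
green test therefore does not establish: between-item correlation beyond
the shared severity and occasion effects (only marginals are matched — the
true joint structure is unknowable from the published tables); covariate
structure (gestational age, sex, co-exposures); site differences in
assessment frequency (fixed at 6/day over days 1–5); and the validation
cohort's actual instrument — its 28-item scale's treatment rule is applied
here to the simulated FNAST score, because the extra items are not
enumerated in the published material.  The synthetic validation cohort is
a labelled stand-in, not a reconstruction.  Two emergent properties worth
noting.  First, because rules trigger on the rising limb of the
trajectory, the realized median treatment day is 2–3 with peak day at 3 —
consistent with the published median of 3 (IQR 2–4), though not calibrated
to it.  Second, taking the *max-score* assessment of the day as the
analysis point induces a weak positive association with treatment for
every weighted sign, even signs with zero severity loading: in
selection-recovery simulations, null signs enter the stepwise model at a
rate (~0.2) well above the nominal retention level.  This is a property of
the analysis-point design, not a defect of the selection code, and it is
why the recovery criterion compares planted-sign recall against the
null-sign inclusion rate rather than against a nominal alpha.

The deterministic marginal-exact fixture (`fixture_analysis_rows()`) is a
different object: per-cohort sign counts equal the published counts
*exactly*, with an arbitrary but fixed joint structure (staggered cyclic
blocks).  It exists for screening-stage regression tests, where only
marginals matter; its joint structure, treated flags and scores are
explicitly not meaningful.

## Degenerate inputs and tie-breaks, in one place

* Day of birth is day 1; "day 3 of life" is the third calendar day.
* Ties for "highest score on the analysis day": the earliest assessment.
* The two vomiting grades (regurgitation, projectile) are one graded item
  whose binary sign is "regurgitation" — projectile vomiting was never
  observed, so the collapse is data-neutral and mirrors the any-sign
  dichotomization rule.
* Grades within an item are mutually exclusive; records carry the single
  highest applicable grade.
* Chi-square on an all-or-none sign: statistic 0, *P* = 1.  Zero cohort
  totals: an error.
* Endorsement AUC with no positives or no negatives: `NA`, reported as
  undefined.  All cohort rates equal: exactly 0.5 (pure ties).
* Weighted kappa with degenerate marginals (`P_e = 1`): `NA`.
* `select_thresholds()` on a constant simplified score: an error.
* Stepwise entry ties: lexicographic by sign id.  Kappa-grid ties:
  smallest `t1`, then smallest `t2`.

## Known limitations

The package reproduces the published *procedure* and every printed
statistic that is recomputable from printed tables.  It cannot reproduce
patient-level results (the final model's odds ratios, the 0.86/0.90 model
AUCs, the median time to treatment) — those are covered only as
property-style checks on synthetic data: parameter recovery within
sampling error, planted-sign recovery exceeding null-sign inclusion, and
the 8-sign model discriminating slightly worse than the full sign set on
the same data.  No multiplicity adjustment is applied across the per-sign
screening tests (none was applied originally).  The kappa and AUC
confidence intervals use asymptotic variances whose match to the published
intervals is unverifiable.
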