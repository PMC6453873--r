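---
title: "Sequential biomarker decision trees for HNF1A MODY: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential biomarker decision trees for HNF1A MODY: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modytree)
```

## The problem

Maturity-onset diabetes of the young (MODY) is a family of monogenic,
autosomal-dominant diabetes forms; the two most common subtypes are caused
by mutations in *HNF1A* and *GCK*. A molecular diagnosis changes treatment,
but sequencing every diabetic patient is not feasible, so the practical
question is triage: given routine clinical measurements — fasting serum
C-peptide (ng/ml), BMI (kg/m²) — and two candidate HNF1A biomarkers —
high-sensitivity C-reactive protein (hsCRP, mg/l; transcriptionally
regulated by HNF1A and therefore low in mutation carriers) and
1,5-anhydroglucitol (1,5-AG, µg/ml; depleted by glycosuria, hence low when
the renal glucose threshold is lowered, as in HNF1A MODY, or when
hyperglycaemic excursions are frequent, as in type 1 diabetes) — which
patients should be prioritised for *HNF1A* sequencing?

No single marker separates HNF1A MODY from type 1 diabetes, type 2
diabetes and GCK MODY simultaneously, because each contrast has a
different driver. The method implemented here embraces that: it builds a
**sequential decision tree** that first removes the groups that are easy
to identify, then deploys the HNF1A biomarkers only where they work — the
HNF1A-vs-GCK contrast.

## The procedure

All discrimination is measured by the C-statistic (area under the ROC
curve), estimated tie-aware over all (positive, negative) pairs:

$$\hat A = \frac{1}{n_+ n_-}\sum_{i,j}\Big[\mathbf 1(s_i > s_j) + \tfrac12\,\mathbf 1(s_i = s_j)\Big].$$

Its variance, confidence intervals, and the paired test for two scores on
the same subjects use DeLong's structural components (the per-subject
placement values), so correlated AUCs are compared without resampling.
95% intervals are Wald on the AUC scale, clipped to [0, 1]; that matches
the symmetric interval style of clinical reports. The package implements
this machinery directly (`c_statistic()`, `delong_paired_test()`,
`roc_curve()`, `select_threshold()`); in the test suite it is
cross-checked against brute-force pair counting, a paired bootstrap, and
the independent pROC implementation.

Tree construction (`build_tree()`) repeats three moves until two groups
remain:

1. **Forward selection per group** (`forward_select_markers()`). For each
   remaining group, start from the single marker with the best
   orientation-corrected one-vs-rest C-statistic. Then repeatedly refit a
   logistic regression with each unused pool marker added and accept the
   addition with the largest C-statistic gain, *provided* its DeLong
   paired test against the current model is significant at `alpha`
   (default 0.05). The gate keeps the index short and guards against
   optimistic drift.
2. **Target the best-identified group.** Among the remaining groups, the
   one whose selected marker set attains the highest C-statistic becomes
   this step's target. Its logistic coefficients are reduced to a
   composite index `marker1 + w2*marker2 + …` (`index_from_fit()`): every
   coefficient is divided by the lead coefficient so the lead weight is 1
   and the index stays in raw clinical units; the intercept is discarded
   because the decision threshold absorbs it. The threshold is chosen by
   maximising Youden's J on the index ROC curve.
3. **Peel.** The target group's records are removed and the procedure
   repeats. When two groups remain, the last index splits them and both
   become leaves.

Classification (`classify()`) walks the steps in order; the first step
whose index crosses its threshold on the target side assigns its group,
and survivors of all steps receive the remaining terminal label.
Evaluation (`evaluate_tree()`) applies the cascade to a labelled cohort
*retaining misclassified records at each step*, exactly as the tree would
operate in clinic, and reports the 4×4 confusion matrix, per-group correct
percentages (half-up, one decimal) and per-step branch tallies.

The published tree ships both as a constructor (`published_tree()`) and as
a JSON fixture (`inst/extdata/published_tree.json`): C-peptide < 0.6 ng/ml
→ type 1 diabetes; C-peptide + 0.16×BMI > 6.29 → type 2 diabetes;
1,5-AG + 1.56×hsCRP < 10.16 → HNF1A MODY, otherwise GCK MODY.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | significance gate for retaining an added marker |
| `pool` | 1,5-AG, hsCRP, BMI, fasting glucose, C-peptide | candidate disease markers |
| `c_peptide_floor` | 0.01 ng/ml | assay detection floor; all simulated C-peptide clamped from below |
| T1D floor probability | 0.50 | mass of the point-mass-at-floor component (see below) |
| `boundary` | `"exclusive"` | a score exactly at a threshold follows the non-target branch |
| group sizes | 77 / 88 / 99 / 92 | HNF1A / GCK / T1D / T2D patients per simulated cohort |

## The synthetic cohort generator

No patient-level data accompany the published summaries, so every stage is
exercised on synthetic cohorts (`simulate_cohort()`) that emulate the
published group-level distributions:

* **Mean ± SD variables** (age, diabetes duration, age at diagnosis, BMI,
  creatinine, HbA1c, fasting glucose) are normal, truncated by inverse-CDF
  sampling at plausibility bounds (e.g. BMI in (10, 80) kg/m²,
  fasting glucose in (2, 30) mmol/l) — the summaries were reported
  symmetric, and truncation only prevents impossible values.
* **Median (Q1, Q3) biomarkers** (hsCRP, 1,5-AG, C-peptide) are drawn from
  a *two-piece (split) log-normal*: log X is Gaussian with spread
  `sigma_lo` below its median and `sigma_hi` above it, with
  `mu = log(median)`, `sigma_lo = (log median − log q1)/z` and
  `sigma_hi = (log q3 − log median)/z`, `z = qnorm(0.75)`. A single-spread
  log-normal anchored at the median cannot reproduce asymmetric printed
  quartiles (several triples here are left-skewed on the log scale, e.g.
  HNF1A C-peptide 1.45 (1.07, 1.80)); the two-piece law matches all three
  quartiles exactly and collapses to the ordinary log-normal when the
  quartiles are log-symmetric. `fit_lognormal_from_quantiles()` also
  reports the symmetric pooled spread `(log q3 − log q1)/(2z)` for users
  who want the one-parameter family.
* **Type 1 diabetes C-peptide** is a mixture: with probability 0.5 the
  value is the detection floor (0.01 ng/ml), otherwise it is log-normal
  with median 0.10 and log-SD 0.8, then clamped at the floor. The printed
  summary (median = Q1 = 0.01, Q3 = 0.10) forces at least half the mass to
  the floor and pins the tail median at 0.10; the tail spread is not
  identified by the quartiles, and 0.8 was fixed once as a moderate
  biological spread for residual insulin secretion. The floor probability
  is exposed because the true undetectable fraction is unknown beyond
  "most patients".
* **Sex and treatment** are categorical with the published percentages.
* **Reproducibility.** Each (group, variable) block draws from its own
  substream derived deterministically from the root seed, so changing or
  adding one variable's specification never perturbs the others' draws,
  and a fixed seed reproduces the cohort bit for bit.

**What the generator does not emulate.** Markers are independent within a
patient (an optional joint structure was considered, but the published
summaries give no correlations to calibrate one); real cohorts correlate
C-peptide with BMI and hsCRP with age/BMI. Distribution families are an
assumption, not an observation. One visible consequence: simulated HNF1A
hsCRP is as tight as its printed interquartile range (0.46–0.66 mg/l),
which makes hsCRP *more* informative per mg/l in simulation than in the
study — re-derived trees therefore put a much larger weight on hsCRP
(of order 20 rather than 1.56) while reaching a similar step C-statistic.
Passing the structure-recovery tests shows the algorithm recovers the
published tree's *shape* under distributions matching the printed
summaries; it does not validate the published *numerical* thresholds or
weights, which encode the real joint distribution.

## Numerical choices and conventions

* **Ties and orientation.** ROC curves call a subject positive when its
  score is on the positive side of the cutpoint, inclusive (`>= t` for
  "higher is positive", `<= t` for "lower"); the orientation flag flips
  the comparison, never the data. Classification, by contrast, uses the
  strict inequality: a record exactly at a threshold follows the
  non-target branch (configurable via `boundary`). A fixed documented
  convention beats ambiguity at measure-zero points.
* **Youden ties** break towards the smallest threshold; **group ties** in
  step selection break towards the smaller marker set, then the fixed
  order T1D, T2D, HNF1A, GCK; **marker ties** break alphabetically. With
  these rules the build is invariant to record and pool order (tested).
* **Logistic fits** use `stats::glm` (IRLS, deviance tolerance 1e-10,
  max 100 iterations) with markers untransformed, intercept only plus the
  markers, and no regularisation. Complete or quasi-complete separation is
  detected (boundary-probability warning plus a separating linear
  predictor) and surfaced as an error; during forward selection a
  separated candidate is skipped with a warning rather than silently
  shrunk. A single marker that separates perfectly still yields a valid
  weight-1 index oriented by its AUC.
* **The DeLong paired test** is the package's choice for the "significant
  C-statistic improvement" gate — the standard test for nested correlated
  ROC comparisons; the published description names no test. Whether the
  published confidence intervals were DeLong-based is likewise unstated,
  so no attempt is made to match interval widths exactly.
* **Degenerate inputs.** Tree building aborts when any live group falls
  below 10 records or when the best achievable step C-statistic is ≤ 0.5
  (up to 1e-6); both conditions produce explicit errors.
* **Percentages** are rounded half-up to one decimal
  (`round_half_up()`), matching clinical reporting style; `round()`'s
  half-to-even rule would differ at exact halves.

## Problem sizes

The test suite and acceptance script run at the study's own scale: default
cohorts of 356 patients (77/88/99/92), 25-seed structure-recovery
replication, 1,000-replicate null calibration of the DeLong test at
n = 100, a 2,000-resample bootstrap cross-check of the DeLong variance at
n = 60, and a 10⁵-per-group cohort for simulator fidelity (empirical
quartiles within 2% of their targets). These sizes were chosen to make the
Monte-Carlo bands tight relative to the tested tolerances.

## Worked example

```{r example}
co <- simulate_cohort(simulation_config(seed = 1))
tree <- suppressWarnings(build_tree(co))
tree
evaluate_tree(published_tree(), co)
```

## Known limitations

* Reported step C-statistics are apparent (resubstitution) performance;
  there is no cross-validation or optimism correction, mirroring the
  published analysis. Re-derived thresholds are Youden-optimal on the
  building cohort and will be optimistic on new data.
* The tree emits hard labels; no probabilistic class membership.
* Units are fixed per column and never converted; feeding nmol/l
  C-peptide or IFCC HbA1c will silently misclassify — validation checks
  plausibility, not units.
* The simulator's independence assumption means cohort-level accuracy
  figures from simulation are not estimates of the study's accuracy; only
  orderings and structure are expected to transfer.
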