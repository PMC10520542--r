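---
title: "Predicting postpartum prediabetes after gestational diabetes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting postpartum prediabetes after gestational diabetes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgdm)
```

## The problem

Women diagnosed with gestational diabetes mellitus (GDM) carry a sharply
elevated lifetime risk of type 2 diabetes, and a large fraction pass through
an intermediate prediabetic state detectable at the 6–13-week postpartum
screen. Attendance at that screen is poor, so an antenatal risk score — one
that can be computed from measurements already taken around the diagnostic
oral glucose tolerance test (OGTT) — lets clinicians concentrate follow-up
on the women most likely to need it.

`ppgdm` implements that analysis end to end on synthetic cohorts with the
statistical structure of a UK multi-ethnic GDM audit cohort (394 women with
known postpartum status; 92 prediabetes, 302 normal glucose tolerance;
prevalence 23.35%):

1. outcome labelling from postpartum biochemistry under NICE (default),
   WHO or ADA criteria;
2. a seeded synthetic-cohort generator;
3. leakage-safe preprocessing (chained-equations imputation,
   standardisation, balanced class weights), all fitted fold-locally;
4. nested cross-validation of an L1-penalised class-weighted logistic
   model and tree-ensemble baselines, pooling held-out predictions;
5. a two-variable composite risk score on raw measurement units;
6. Kullback–Leibler (K-L) divergence cut-point selection with
   rule-in/rule-out diagnostics, information graphs, and the Bregman
   representation of the total divergence;
7. decision curve analysis and a two-sample power analysis.

## Outcome labelling

A woman's postpartum state is derived from up to three measures: fasting
glucose (P-FG, mmol/L), 2-h postprandial glucose (P-PG, mmol/L) and HbA1c
(mmol/mol). Incident diabetes (P-FG ≥ 7.0 or P-PG ≥ 11.1 or HbA1c ≥ 48)
takes precedence over prediabetes (NICE: P-FG ≥ 5.6 or P-PG ≥ 7.8 or
HbA1c ≥ 40); a record with at least one measure and no threshold crossing
is normal glucose tolerance (NGT); a record with no measure is unlabelled
and excluded from modelling. All comparisons are inclusive (≥). WHO differs
by a higher fasting bound (6.1) and no HbA1c criterion; ADA by an HbA1c
bound of 39 mmol/mol. Units are fixed; the mg/dL equivalents sometimes
quoted alongside are documentation, not accepted input. Labelling is
monotone by construction: raising any measure can only move a record toward
a more severe category, and the labeller reports which measures fired.

A note on scope: a woman with only an HbA1c (no OGTT) is labelled from
HbA1c alone — the OR-rule admits any non-empty subset of measures.

## The synthetic cohort generator

The real cohort is not public, so every stage is exercised on generated
data whose class-conditional means and SDs match the audit cohort's
published summary moments (see `default_class_moments()`): e.g. antenatal
fasting glucose 5.38 ± 0.91 mmol/L in the prediabetes class against
4.82 ± 0.81 in the NGT class, and HbA1c 38.13 ± 4.61 against 34.72 ± 4.42
mmol/mol.

Two generative modes:

* **Latent-logistic** (default): antenatal fasting glucose and HbA1c are
  drawn from the overall-cohort bivariate Gaussian (correlation 0.3 by
  default — the summary moments give only marginals, and 0.3 is a
  realistic glycaemia–HbA1c association at these time scales), and the
  outcome is Bernoulli with
  `logit P = b0 + 0.58·A-FG + 0.10·A-HbA1c`.
  With the reference slopes and intercept −8.36 the implied prevalence
  over the covariate distribution is ≈ 0.13, noticeably below the study
  prevalence of 0.2335; when a target prevalence is requested the
  generator therefore calibrates the intercept by root-finding over the
  drawn covariates, leaving the slopes untouched. This preserves the
  parameter-recovery contract (an unpenalised refit at n = 20,000 recovers
  both slopes within ±15%) while matching the cohort's class balance.
  Setting `prevalence = NULL` uses the intercept as given.
* **Class-conditional**: the outcome is drawn first at the target
  prevalence, then features come from the class-specific Gaussians. This
  mode exists for moment-matching checks and for building no-signal
  cohorts (identical class moments).

All Gaussian draws are truncated at physiologic floors (glucose
> 2 mmol/L, HbA1c > 15 mmol/mol) by redraw; BMI is drawn and weight derived
as `bmi × height²`, so the BMI consistency audit holds exactly. Postpartum
biochemistry is drawn from the class-conditional Gaussians under rejection
so that NICE labelling recovers the generated outcome — positives satisfy
the prediabetes rule and not the diabetes rule, negatives sit below every
threshold.

Missingness is injected MCAR, cell-wise and only on antenatal covariates;
outcome-defining fields are never masked. The generator makes no attempt to
model the informative dropout of women who skip postpartum screening, nor
covariate dependence beyond the fasting-glucose–HbA1c correlation, nor
measurement rounding: passing tests demonstrate the pipeline's internal
correctness under this stylised data-generating process, not performance on
real clinical data.

## Leakage-safe preprocessing

All three preprocessing steps are fitted on training rows only and then
applied to held-out rows, inside every outer fold.

**Imputation** is single-completion chained equations: missing cells start
at the training means, then features are cycled for 10 sweeps (default),
each sweep regressing the feature on all others by ordinary least squares
over the training rows observed for that feature and replacing its missing
cells with fitted values. One-hot dummies are clipped to [0, 1]. The scheme
is deliberately deterministic — no posterior draws, no predictive-mean
matching, no multiple-imputation pooling — because the evaluation
aggregates exactly one prediction per held-out sample, which calls for one
completed dataset per fold. As a consequence the `seed` argument is
recorded but unused, and the completion is invariant to the row order of
the training matrix. A feature with zero observed training values is a hard
error naming the feature.

**Standardisation** is the z-score with training mean and SD; constant
features are flagged and given scale 1 so they standardise to zeros rather
than NaN.

**Class weights** follow the balancing rule `w_k = 1/(2 · fraction_k)`,
which equalises the total loss mass of the classes
(`n₀w₀ = n₁w₁ = n/2`). At the study split (92/302) this gives 2.1413 for
the prediabetes class and 0.6523 for NGT. Weights multiply per-sample loss
contributions in every learner.

## Nested cross-validation

The outer loop (leave-one-out by default; stratified 4-fold available and
used for the costlier ensembles) exists solely for assessment; the inner
stratified 4-fold loop, run inside each outer training fold, picks
hyperparameters by mean inner accuracy (predicted class at probability
0.5). Accuracy is the default selection metric; AUC is available by
configuration. Ties break toward the first candidate in declared grid
order, which makes the search deterministic. One global seed is fanned out
to per-outer-fold seeds drawn once up front, so results do not depend on
evaluation order.

The headline learner is L1-penalised class-weighted logistic regression,
parameterised by the inverse penalty C on a 10-point log-spaced grid from
10⁻³ to 10³ (the grid is configuration). The objective is
`Σᵢ wᵢ·loss_i + ‖β‖₁/C`; the optimiser is glmnet's coordinate descent with
a tight convergence threshold, with the penalty mapped so that the fit is
exactly invariant to duplicating samples while halving their weights (a
property the test suite asserts to near machine precision). Features are
standardised upstream, never inside the solver. The nonzero-coefficient
set of each outer fold is recorded; `feature_stability()` reports, per
feature, the count and fraction of outer folds selecting it — on synthetic
cohorts the two informative predictors are selected in well over 80% of
the 394 leave-one-out folds.

Tree baselines (decision tree, bootstrap-aggregated trees with
probability averaging over B resamples, random forest, gradient-boosted
trees) ride on standard implementations (rpart, randomForest, xgboost)
behind the same interface; the bespoke content is the balancing, nesting,
pooling and stability accounting around them. The rpart-based learners
expose `min_samples_split`/`min_samples_leaf`/`criterion`; a leaf-count
cap is not available in rpart's control set and is approximated by those
controls plus the complexity parameter.

`roc_auc()` thresholds at the distinct predicted probabilities and
integrates by trapezoid, which equals the Mann–Whitney concordance
probability with ties counted ½ — asserted against an O(n²) pairwise
oracle. `brier()` is the mean squared probability error.

**A caution on pooled leave-one-out scores.** Pooling the n held-out
probabilities into a single ROC is the evaluation used here, but under a
null (no-signal) data-generating process the pooled LOOCV AUC is
pessimistically biased below 0.5: each leave-one-out model is fitted on a
training set slightly depleted of the held-out sample's class pattern, and
with balanced weights the effect survives through the slopes. The package's
chance-level test therefore uses the stratified outer scheme at n = 1000,
where the pooled-CV spread is tight; the permutation-null check on the
leave-one-out path uses a band of [0.40, 0.60] that accommodates the
artifact.

## The composite risk score

The deployment model refits the class-weighted L1 logistic on all labelled
rows (hyperparameters from the same inner-CV rule) and back-transforms the
coefficients from the standardised to the raw scale:
`b_raw = b_std/sd`, `b0_raw = b0_std − Σ b_std·mean/sd`. Raw-scale and
standardised-scale models give identical probabilities on every sample (a
tested identity), and the resulting score applies directly to measurements
in mmol/L and mmol/mol. The default predictor set is `{a_fg, a_hba1c}` —
the two predictors the stability analysis singles out — with full-feature
fitting available by configuration. `reference_risk_model()` carries the
reference coefficients (−8.36, 0.58, 0.10); at the cohort-mean inputs
(4.95, 35.52) it yields a risk of 0.126.

Operating points at predetermined sensitivities (60, 70, 75, 80, 90%) are
selected over the discrete set of attainable cut-points: candidates are 0
and the observed scores, and the chosen cut-point is the largest candidate
at which the fraction of positive scores strictly above it still meets the
target; the reported row then uses the package-wide classification rule
`score ≥ c` (ties positive). This makes a 100% target land strictly below
the minimum positive score, and achieved sensitivity is non-decreasing as
the target decreases.

## K-L divergence cut-point selection

At cut-point c the dichotomised score defines two Bernoulli response
distributions: the diseased respond positive with probability g₁(c)
(sensitivity) and the non-diseased negative with probability g₂(c)
(specificity). The rule-in divergence
`D(g₁‖g₂) = g₁ln(g₁/(1−g₂)) + (1−g₁)ln((1−g₁)/g₂)` measures how strongly a
positive result separates diseased from non-diseased; its mirror
`D(g₂‖g₁)` governs rule-out strength. Derived quantities: the odds
multipliers `P = e^D` (pre-to-post-test odds ratio), information
distinguishability `ID = 1 − e^{−D}`, and the symmetric objective
`TKL(c) = D(g₁‖g₂) + D(g₂‖g₁)`.

`scan_cutpoints()` evaluates the full metric row at 1000 grid points,
0.000–0.999 in steps of 0.001 (a half-open reading of "0 to 1 in 1000
steps": both endpoints cannot be on a 1000-point grid, and c = 1 would
classify nobody positive). Three tests are selected: the rule-in test at
argmax D(g₁‖g₂), the rule-out test at argmax D(g₂‖g₁), and the combined
test at argmax TKL, ties toward the smaller c.

Numerical policy: every probability entering a log is clamped to
[10⁻¹², 1−10⁻¹²], so divergences at degenerate rows (g₁ or g₂ at 0 or 1)
are large finite values carrying a `degenerate` flag rather than ±∞. Those
flagged rows are excluded from the argmax selection: at any c below the
minimum positive score g₁ = 1 makes the rule-out divergence *genuinely*
infinite through a structural zero of the estimated response distribution,
which is an artifact of finite-sample estimation, not usable rule-out
information. If every row is degenerate (a pathological score set), the
selection falls back to all rows and the anti-informative flag (Youden
J ≤ 0 at the combined optimum) marks the result.

The `ta` column is the integer-rounded percent of scores strictly below c —
the fraction of the cohort in whom testing can be avoided at that
threshold.

**Information graphs.** For fixed (g₁, g₂) and pre-test probability
x = Pr(D₁), a positive result occurs with probability
`Pr(T₁) = x·g₁ + (1−x)(1−g₂)`, and the information carried by a positive
(negative) result is implemented as the K-L divergence of the post-test
disease distribution from the pre-test one. Written that way, the
expected-information decomposition
`I_E = Pr(T₁)·I₊ + (1−Pr(T₁))·I₋` holds exactly (it is the mutual
information of the 2×2 joint, and the tests assert both the identity and
agreement with a direct joint-entropy oracle). Some textbook presentations
write I₊/I₋ without the normalising terms that make this identity exact;
the posterior-versus-prior form is the one under which the decomposition
is an identity, and that identity is the acceptance test for the choice.

**Bregman representation.** With the negative Shannon entropy
`h(p) = p·ln p + (1−p)·ln(1−p)`, the Bregman divergence of h between p and
q is exactly the Bernoulli K-L divergence, so the sum of vertical distances
between h and its tangents at `p = 1−g₂` (evaluated at g₁) and at `p = g₁`
(evaluated at 1−g₂) equals `kl_in + kl_out`. The package computes the
tangent construction literally and the identity is asserted to 10⁻¹⁰ over
an interior lattice.

## Decision curves and power

Decision curve analysis reports
`nb_model(pt) = (TP − FP·pt/(1−pt))/N` against treat-all and treat-none
comparators over pt ∈ {0.01, …, 0.99}. N defaults to the prediction-set
size; it is configurable (e.g. to the size of a full cohort of which the
labelled subset is a part) because the denominator convention matters when
comparing curves across cohorts of different coverage. The plain net
benefit formula is implemented; no standardised rescaling.

The power module answers "was n = 394 (92 + 302) enough?": Cohen's d with
pooled SD (the class-conditional fasting-glucose moments as printed give
d = 0.671; unrounded data give slightly more), and the minimum sample size
solves the noncentral-t power equation for the smallest real n₁ with
n₂ = ratio·n₁ reaching the target power, then rounds each group up
independently. The noncentral-t (not the normal approximation) matters:
at d = 0.681, α = 0.05, power 0.90 and ratio 0.305 it gives exactly
(99, 31), total 130, and ceiling per group — not ceiling of the total — is
what reproduces that split. Power curves over (n, d, α) come from the same
power function and are monotone in n and d.

## Problem sizes and determinism

The test suite builds every fixture in code. Sizes were chosen so each
check is statistically meaningful at interactive scale: moment convergence
and parameter recovery at n = 20,000 (where ±15% slope recovery is a
~10-sigma-wide band), feature stability on the study-sized n = 394 with
ten pure-noise nuisance features under full leave-one-out, the
permutation null at n = 200, and the chance-level check at n = 1000 under
the stratified outer scheme. Every stochastic step flows from explicit
seeds: the generator from its spec seed, the CV engine from one global
seed fanned out to per-fold seeds, and `run_pipeline()` writes a log from
which every number in the report bundle can be regenerated bit-for-bit.

## Known limitations

* The synthetic cohort is a stylised stand-in: MCAR missingness only, no
  informative dropout, Gaussian marginals with a single fixed
  cross-correlation, and class moments taken from rounded summary tables.
* Single-completion imputation understates imputation uncertainty by
  design (no Rubin pooling); this matches the one-prediction-per-sample
  evaluation but would be the wrong choice for inferential standard
  errors.
* The L1 path is a plain lasso penalty; no elastic-net mixing.
* Pooled LOOCV scores carry the null bias discussed above; comparisons
  between learners evaluated under different outer schemes (leave-one-out
  vs stratified 4-fold) inherit a small scheme effect.
* rpart cannot cap leaf count directly; the decision-tree grid controls
  splits and leaf sizes instead.
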