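# ppgdm — postpartum prediabetes risk prediction after gestational diabetes

Women diagnosed with gestational diabetes mellitus (GDM) face a high risk
of postpartum prediabetes and, later, type 2 diabetes — but attendance at
the 6–13-week postpartum glucose screen is poor, and there has been no
personalised way to decide which women most need chasing. `ppgdm`
implements, as a tested R analysis workflow, an antenatal prediction
pipeline for postpartum prediabetes and the information-theoretic framework
for turning its probabilities into clinically usable rule-in / rule-out
tests.

The core pieces, in the field's standard notation:

* **Outcome labelling** from postpartum biochemistry: prediabetes if
  P-FG ≥ 5.6 mmol/L or 2-h P-PG ≥ 7.8 mmol/L or HbA1c ≥ 40 mmol/mol
  (NICE; WHO and ADA variants available), incident diabetes at
  7.0 / 11.1 / 48 taking precedence.
* **Nested cross-validation**: outer leave-one-out (CV1) for assessment,
  inner stratified 4-fold (CV2) for hyperparameter search, with
  imputation (chained equations), standardisation and balanced class
  weights `w_k = 1/(2·fraction_k)` all fitted inside each training fold.
  Held-out predictions are pooled into one ROC; the L1-penalised
  class-weighted logistic model records which features each fold selects.
* **Composite risk score** on raw units:
  `P(prediabetes) = 1/(1 + e^{−(b₀ + b₁·A-FG + b₂·A-HbA1c)})`, with
  coefficients back-transformed from the standardised fit (reference
  values −8.36, 0.58, 0.10).
* **K-L divergence cut-point selection**: at cut-point c, sensitivity
  g₁(c) and specificity g₂(c) define two Bernoulli response
  distributions; the divergences `D(g₁‖g₂)` and `D(g₂‖g₁)` are maximised
  over 1000 cut-points to select a rule-in test, a rule-out test, and a
  combined test maximising `TKL = D(g₁‖g₂)+D(g₂‖g₁)`, with odds
  multipliers `P = e^D`, information distinguishability `1 − e^{−D}`,
  information graphs and the Bregman-tangent representation of TKL.
* **Decision curve analysis** (`(TP − FP·pt/(1−pt))/N`) and a
  **power analysis** (Cohen's d with pooled SD; minimum sample size via
  the noncentral-t power function with unequal allocation).

The real audit cohort is not deposited, so the package ships a seeded
synthetic-cohort generator emulating its published class-conditional
moments (n = 394; 92 prediabetes / 302 NGT; prevalence 23.35%), and every
stage is tested against that generator plus closed-form and brute-force
oracles. See the methods vignette
(`vignettes/postpartum-prediabetes-workflow.Rmd`) for the model, the
numerical policies and the design decisions.

## Worked example

```r
library(ppgdm)

# a study-sized synthetic cohort: 394 women, ~23% prediabetes
cohort <- generate_cohort(generator_spec(n = 394, prevalence = 0.2335,
                                         missing_rate = 0.05, seed = 20260926))

# nested CV: outer leave-one-out, inner stratified 4-fold
preds <- nested_cv_evaluate(cohort, model_spec("sparse_logistic"),
                            cv_config(outer = "leave_one_out", seed = 1),
                            features = antenatal_features(TRUE))
roc_auc(preds)$auc            # 0.7502  — pooled held-out discrimination
brier(preds)                  # 0.1977  — calibration loss

# which predictors do the 394 leave-one-out fits keep?
head(feature_stability(preds)[order(-feature_stability(preds)$fraction), ], 3)
#  a_fg 394/394, a_hba1c 394/394, bmi 394/394 ...

# information-theoretic cut-point selection on the pooled predictions
sel <- scan_cutpoints(preds)$selection
sel$c_in; pin_pout(sel$d_in)  # rule-in  test: c = 0.446, P_in  = 1.48
sel$c_out; pin_pout(sel$d_out)# rule-out test: c = 0.370, P_out = 1.57

# the two-variable deployment score, back-transformed to raw units
final <- fit_final_model(cohort, features = c("a_fg", "a_hba1c"),
                         cv = cv_config(seed = 2))
final$coefficients            # a_fg 0.9441, a_hba1c 0.0898 (per mmol/L, per mmol/mol)
composite_risk(reference_risk_model(), c(a_fg = 4.95, a_hba1c = 35.52))
# 0.126 — risk at the cohort-mean antenatal measurements

# was the cohort big enough? d = 0.671 from the printed fasting-glucose
# moments; minimum n at 90% power with 92:302 allocation:
solve_sample_size(power_spec(d = 0.681, alpha = 0.05, power = 0.90,
                             ratio = 0.305))
# $n1 99  $n2 31  $total 130
```

The pooled AUC of 0.75 says the two glycaemic measurements separate future
prediabetes from NGT usefully but not perfectly; `P_in = 1.48` means a
positive rule-in test multiplies a woman's disease odds by about 1.5, and
the rule-out cut-point clears roughly the bottom half of the cohort from
immediate follow-up. (Numbers are from the synthetic cohort above and are
reproduced by `analysis/01_simulate.R` … `05_utility.R`, which write the
same tables under `results/`.)

The numbered scripts under `analysis/` run the same workflow as a narrative
pipeline — simulate, evaluate, score, select cut-points, decision curves
and power — each a thin driver over the package functions;
`run_pipeline()` does all of it in one call from a `run_config()` or a
YAML file.

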