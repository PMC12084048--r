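# mosr — Multi-Objective Symbolic Regression for Perioperative Risk Modelling

`mosr` evolves **readable mathematical formulae** for binary clinical
classification by genetic programming, and packages the full evaluation
protocol of a perioperative risk study around them: cardiopulmonary exercise
test (CPET) signal processing, a synthetic cohort generator, clinical-score
baselines, reference classifiers, leakage-safe evaluation, and model-agnostic
Shapley feature attribution.

## Who it is for

Biostatisticians and perioperative researchers who want risk models that are
*inspectable formulas* rather than black boxes — e.g. predicting
postoperative morbidity (POMS ≥ 2 on day 3) from preoperative
cardiorespiratory-fitness (CRF) features such as the ventilatory anaerobic
threshold (AT) and peak oxygen uptake — and who need the surrounding study
machinery (splits, cross-validated tuning, repeated test evaluation,
benchmark arms) to be reproducible.

## The method

A candidate model is an expression tree over named features built from
`{+, −, ×, protected ÷, log, exp, sqrt, neg}`. Its raw score `s(x)` maps to a
probability through the logistic link `p = σ(s(x))`, and a population of
trees is evolved under **two jointly minimised objectives**:

* **binary cross-entropy** ` BCE = −(1/n) Σ [y·ln p + (1−y)·ln(1−p)] `
* **complexity-penalised AIC** ` pAIC = 2k + 2n·BCE ` with `k` = node count,

using NSGA-II selection (non-dominated sorting + crowding distance). The
engine returns the Pareto archive of every non-dominated formula found and a
*champion* — the archive member with the best validation-set BCE. Because
complexity is an explicit objective, the champion is typically a short
formula referencing a handful of features: feature selection is intrinsic.

Around the engine:

* `cpet_signals` — sliding median filter, shape-preserving downsampling,
  V-slope anaerobic-threshold detection (two-segment least squares), and the
  30-second peak oxygen uptake;
* `synthetic_cohort` — a latent-variable generator producing cohorts with a
  CRF feature block, a weakly informative clinical block, nine-domain POMS
  outcomes, and 1-Hz fifteen-channel exercise waveforms consistent with the
  tabular features;
* `baselines` — threshold rules (PPOSSUM ≥ 30% risk, ASA ≥ 2, DASI < 34,
  AT < 11 ml/kg/min), a single-covariate AT logistic model, and tuned
  reference classifiers (logistic regression, decision tree, random forest,
  gradient-boosted trees);
* `evaluation` — stratified splits with largest-remainder class allocation,
  10-fold cross-validated grid search, repeated 90% test-subsample
  evaluation with t-based 95% confidence intervals, tie-corrected AUC and
  PR curves;
* `attribution` — Shapley values (exact coalition enumeration up to 12
  features, permutation sampling beyond), with global feature ranking.

## Worked example

Generate a synthetic cohort, fit a formula on its CRF features, and evaluate
on held-out patients:

```r
library(mosr)

co <- generate_cohort(cohort_config(n_patients = 600, n_clinical = 10,
                                    n_crf = 12, seed = 42))
mean(co$poms_class_d3)                      # 0.54  (outcome prevalence)
cor(co$vo2_kg_at, co$poms_count_d3)         # -0.684 (fitness-morbidity link)

d  <- as.data.frame(co)[c(cohort_features(co, "crf"), "poms_class_d3")]
sp <- stratified_split(d, 0.8, seed = 1)
tf <- preprocess_fit(sp$a)
train <- preprocess_apply(tf, sp$a)
test  <- preprocess_apply(tf, sp$b)

fit <- mosr_evolve(train, "poms_class_d3", evolution_config(80, 60, seed = 7))
fit
#> Multi-objective symbolic regression fit
#>   champion: ((((hr_at - vo2_kg_peak) / (hr_at * work_rate_peak)) +
#>              (hr_at - vo2_kg_peak)) + (hr_at - vo2_kg_peak))
#>   train BCE 0.4705 | paic 481.71 | nodes 15 | archive size 3

repeated_test_evaluation(function(nd) predict(fit, nd), test, seed = 2)
#>        metric  mean ci_half
#>      accuracy 0.748 0.00814
#>           auc 0.845 0.00902
#>            f1 0.771 0.00942
#>   sensitivity 0.782 0.01237
#>   specificity 0.708 0.01179
#>           ppv 0.761 0.01238
#>           npv 0.732 0.01162
```

The champion is a readable formula dominated by the heart-rate-at-threshold /
peak-uptake contrast: higher fitness (higher `vo2_kg_peak`, lower `hr_at`)
lowers the predicted risk. The report gives the mean and 95% CI of each
metric over 10 random 90% subsamples of the test set.

`run_experiment()` orchestrates the full multi-arm study (clinical-only /
CRF-only / combined / waveform time-series / scalar subset × model arms),
and `exec/mosr-study` exposes `synth`, `extract`, `fit` and `run`
subcommands for shell use.

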