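---
title: "Multi-objective symbolic regression for perioperative risk: models, generator and protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-objective symbolic regression for perioperative risk: models, generator and protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosr)
```

This vignette is the package's own account of its science: the model and its
assumptions, the synthetic data-generating process and what it does and does
not emulate, the numerical choices, and the design decisions that were
genuinely open.

## The model

A candidate classifier is an expression tree over named features with the
function set `{+, −, ×, ÷, log, exp, sqrt, neg}`. The raw score is mapped to
a probability by the logistic link, `p = σ(s(x))`, clipped into
`[1e-12, 1 − 1e-12]`. The link is a modelling choice, not part of the tree:
cross-entropy training requires a probability, and the sigmoid is the
canonical choice for a binary outcome.

**Protected operators.** Genetic programming composes operators blindly, so
every partial function is closed: `x ÷ 0 → 1`, `log(x ≤ 0) → 0`,
`sqrt(x) → sqrt(|x|)`, and the argument of `exp` is clamped to ±50. These
are standard GP conventions whose single purpose is to keep every fitness
value finite; they also mean a formula's printed form must be read together
with these conventions near degenerate inputs.

**Objectives.** Two objectives are minimised jointly:

* binary cross-entropy on the training rows, and
* a complexity-penalised AIC, `pAIC = 2k + 2n·BCE`, i.e. `2k − 2 ln L`
  under the Bernoulli likelihood with `k` = the tree's node count.

Node count is the natural complexity measure for trees (operators and leaves
alike); `pAIC` is strictly increasing in `k` at fixed loss, so among equally
accurate formulae the smaller always dominates. One consequence worth
stating honestly: at realistic training sizes the likelihood term `2n·BCE`
dwarfs `2k`, so the two objectives are highly correlated and the Pareto
front is thin — often a handful of formulae, sometimes a single one. The
complexity objective then acts mainly as a strong parsimony tie-break rather
than as a source of front diversity. That is the intended behaviour of an
AIC-type penalty, not a defect, but users expecting a broad accuracy-
complexity front should inspect `fit$archive` with that in mind.

**Search.** NSGA-II-style selection: non-dominated sorting, crowding
distance, binary tournaments; subtree crossover (rate 0.8), subtree/point/
constant-perturbation mutation (total rate 0.2); ramped half-and-half
initialisation at depths 2–5; ephemeral random constants uniform on
[−2, 2]; structural caps (default depth 8, 40 nodes) enforced by rejecting
violating offspring. A small immigration stream (5% of each offspring
generation drawn fresh at random) guards against premature convergence —
without it the population occasionally fixates on a single informative
feature and never discovers a second one. All of these are documented
defaults in `evolution_config()` and none is sacred; the defaults were
chosen as standard GP practice.

**Champion selection.** The engine returns the running archive of every
non-dominated individual encountered, and a champion: the archive member
with the lowest *validation* BCE (training BCE when no validation set is
given), ties resolved towards lower `pAIC`, then fewer nodes, then earlier
generation. Selecting on a held-aside validation split rather than on
training loss is the package's documented choice; the alternative (a
Pareto-knee rule) is equally defensible but harder to specify crisply.

## The synthetic cohort generator

No patient-level data ship with the package; the generator exists so that
every downstream stage is exercisable and testable. It emulates a
perioperative CPET cohort of elderly elective-surgery patients:

* ~1,190 patients, 39 clinical + 46 CRF features, ~53% POMS ≥ 2 prevalence;
* a latent cardiorespiratory fitness `z`; the CRF block loads on `z` with
  loadings 0.63–0.89 (within-block correlations roughly 0.4–0.8), and the
  designated `vo2_kg_at` feature loads at 0.95;
* a latent clinical frailty `c` with weak loadings (0.15–0.4) on the
  clinical block — deliberately weakly informative, reproducing the
  direction of the clinical-vs-CRF performance gap;
* a latent *dynamic exercise response* `z2` that enters the outcome risk
  but surfaces **only** in waveform shape (the post-exercise recovery time
  constant), never in any scalar feature — this is what gives the
  time-series experiment something real to find beyond the hand-extracted
  summaries;
* outcome risk `r = shift − 2.4·z − 1.5·z2 + 0.5·c + ε`, `ε ~ N(0, 0.6²)`,
  with the nine POMS domains drawn as conditionally independent Bernoullis
  whose log-odds increase with `r`; morbidity class is 1 iff at least two
  non-excluded domains are positive. The global `shift` is found by root
  finding on the drawn risks so the *expected* prevalence equals the target
  exactly (the Poisson-binomial tail over the nine domains is evaluated in
  closed form).

The effect sizes are calibrated, once, by simulation: with the defaults the
absolute Pearson correlation between `vo2_kg_at` and the day-3
POMS-positive-domain count is ≈ 0.69, matching the strength of the
fitness-morbidity association the generator is meant to emulate. Later
assessment days (5, 7) carry a negative log-odds shift, so their counts are
lower but positively correlated with day 3 through the shared risk.

Waveforms are 15-channel, 1-Hz recordings built around each patient's
planted AT and peak targets: a rest plateau (120 s), a linear ramp (480 s),
a 30-s sustained peak, and an exponential recovery whose time constant
carries `z2`. CO₂ output follows the V-slope geometry — linear in O₂ uptake
with slope 0.85 below the threshold and 1.15 above — so the planted AT is
recoverable exactly from noiseless data. The waveform targets are direct
functions of the latents; the tabular features are their noisy readouts.
That ordering (time-series view cleaner than scalar view) is a construction,
chosen so the waveform experiment can demonstrate an advantage; it is an
assumption about the world, not a measurement of it.

**What passing tests do and do not show.** The generator produces Gaussian
latent structure, monotone logistic domain responses, and idealised
piecewise-linear exercise kinetics. Real CPET traces have breath-by-breath
noise structure, protocol deviations, early test termination and missing
channels; real cohorts have informative missingness and case-mix effects
none of which are simulated. Green tests demonstrate that the machinery is
correct and that the protocol behaves as designed under the stated
assumptions — they say nothing about clinical performance on real patients.

## Signal processing choices

* **Median filter**: sliding window (default 5 s) with shrinking symmetric
  windows at the edges, so output length equals input length and endpoints
  pass through. The shrinking-edge rule is implemented directly because the
  standard running-median end rules (e.g. Tukey's) differ at the first and
  last few samples.
* **Downsampling**: linear interpolation at equally spaced points — exact
  on ramps, endpoint-preserving, monotonicity-preserving. Block averaging
  was rejected because it shifts breakpoint locations.
* **V-slope AT detection**: exhaustive two-segment least squares over the
  ramp window (O(1) per candidate via cumulative sums), requiring the second
  slope to exceed the first, each segment to span ≥ 60 samples, and the
  two-segment fit to beat the single line by ≥ 5% relative RSS — otherwise
  the result is flagged indeterminate rather than forced. Ventilatory-
  equivalent and end-tidal corroboration are deliberately not part of the
  primary detector: the three clinical criteria come with no published
  arbitration rule, so the geometric criterion is primary and the others
  are left to the analyst.
* **Peak oxygen uptake**: the highest 30-sample rolling mean with the
  window ending in the final 60 s of ramped exercise (default), or the
  literal mean of the last 30 samples (`mode = "last30"`). "Highest average
  over the last 30 seconds" is ambiguous between these two readings; the
  rolling form dominates the literal one on any input, and both are
  exposed.

## Evaluation protocol

Splits use round-half-up on `ratio·n` with largest-remainder allocation
across outcome classes: 1190 → 952/238 at 80:20, 952 → 857/95 at 90:10.
Test subsampling uses `floor(0.9·238) = 214`. The mixed rounding (round for
splits, floor for the subsample) is anchored to those printed partition
sizes. Continuous features are min-max scaled with parameters learned on
the training partition only; non-ordinal categoricals are one-hot encoded;
values outside the training range are *not* clipped but flagged. Metrics
with zero denominators are reported as flagged-missing and excluded from
the mean with the exclusion counted. Confidence intervals are Student-t
over the 10 subsample runs (df = 9) — the reporting convention when a mean
and 95% CI over 10 executions is requested and no method is stated. The
decision threshold is 0.5 for every arm, for comparability. AUC is computed
by tie-corrected concordance (mid-ranks), which the test suite verifies
against brute-force pair counting and trapezoidal ROC integration.

For stochastic seeding, all stage seeds derive deterministically from one
master seed. In R the idiomatic realisation of "one injected generator" is
seeding the global RNG stream once per operation from the configuration;
the package does exactly that (`set.seed` at each entry point), so identical
configurations reproduce identical outputs byte for byte.

## Shapley attribution

Model-agnostic Shapley values on the probability scale, with absent features
marginalised by substituting background-sample values (the marginal,
KernelSHAP-style assumption; conditional substitution would require a
density model the package does not have). Feature sets of ≤ 12 features are
attributed by exact coalition enumeration; larger sets by permutation
sampling. Efficiency, symmetry and dummy axioms hold exactly on the
enumeration path and within Monte-Carlo tolerance on the sampling path. The
default background is a ~100-row sample of the training partition;
attributions are averages over it, so they inherit its sampling noise.

## Scaled experiment profiles

The full-size configuration (300 individuals × 500 generations, n = 1190)
is the package default for real use. The test suite and the acceptance
script run deliberately scaled profiles chosen as the smallest sizes at
which each property is stably demonstrated:

* planted-rule recovery: n = 1000, 7 features, population 100 × 100
  generations, 10 seeds;
* tabular arm comparison: n = 600 patients, 12 clinical + 14 CRF features,
  population 60 × 50 generations;
* waveform arm comparison: same cohort, waveforms for half the patients,
  12 samples per channel after downsampling, population 80 × 80
  generations, and one shared split for the time-series arm and the
  scalar-subset arm so the two are compared on the identical test patients
  (a paired comparison, as the subset arm exists precisely to be evaluated
  on the same patients as the time-series arm).

The waveform profile's larger search budget reflects the higher-dimensional
feature space (15 channels × 12 positions); the coarse 12-point resolution
concentrates the recovery-phase signal into few columns, which is what a
shape-preserving downsample is for.

## Known limitations

* The `pAIC` form `2k − 2 ln L` with node-count complexity is one concrete
  reading of a complexity-penalised AIC; other penalties (e.g. counting
  only constants as parameters) are plausible and the objective is
  swappable.
* No algebraic simplification beyond what evolution finds: champions can
  contain redundant subexpressions (`a + a + a` rather than `3a`).
* The reference-classifier arms are adapters over established
  implementations (glm, rpart, randomForest, xgboost) with small default
  grids; they are comparison scaffolding, not tuned competitors.
* Single-threaded by design; the engine evaluates a few hundred trees per
  generation vectorised over rows, which is fast enough for the intended
  cohort sizes but not for genome-scale feature spaces.
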