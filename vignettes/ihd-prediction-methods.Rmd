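---
title: "Methods: balanced random forests for predicting intraoperative hemodynamic instability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: balanced random forests for predicting intraoperative hemodynamic instability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihdforest)
```

## The clinical problem

Pheochromocytoma is a catecholamine-secreting tumor of the adrenal medulla.
Its resection can trigger intraoperative hemodynamic instability (IHD) —
systolic blood pressure above 200 mmHg or mean arterial pressure below
60 mmHg, or the need for norepinephrine or transfusion to hold pressure —
which is the life-threatening complication anesthesiologists prepare for.
The question this package addresses is: which routine preoperative
indicators (age, BMI, ASA score, tumor size, the 24-h urine
catecholamine-metabolite ratio, contrast-CT enhancement difference, and so
on) predict IHD, and how well can a classifier trained on a small,
imbalanced surgical cohort (roughly one event per 2.8 non-events) separate
the two outcomes?

The pipeline has five stages: cohort synthesis (or CSV load), Relief-F
feature weighting with threshold retention, a classifier benchmark over
three validation families, a balanced random forest (BRF) for the
imbalanced outcome, and a three-list variable-importance consensus that
produces the final risk-factor set. Each stage is an exported function
(`sample_cohort()`, `relief_f_weights()`, `run_benchmark()`, `train_brf()`,
`consensus_select()`); `run_pipeline()` chains them, and the numbered
scripts under `analysis/` run them as a narrative workflow.

## The synthetic cohort generator

The original patient records are not public, so every downstream stage is
exercised on synthetic cohorts drawn from the *published per-class summary
statistics* of the 283-patient study population (shipped as the versioned
fixture `inst/extdata/table1_specs.json`): 18 predictors, IHD prevalence
74/283 = 26.1%, and for each feature either a class-conditional normal
(mean ± SD, e.g. BMI 24.1 ± 3.5 without IHD vs 21.9 ± 2.7 with IHD), a
Bernoulli/multinomial (stored as the published counts, so probabilities sum
to one exactly), or — for the right-skewed urine metabolite ratio reported
as median (IQR) — a lognormal fitted by `lognormal_from_quantiles()`.

Design choices a maintainer should know:

* **Distributional families.** The published table distinguishes
  normally-distributed from non-normal continuous variables, which fixes
  normal vs lognormal; nothing finer is identifiable from summary
  statistics.
* **Lognormal fit.** `meanlog = log(median)`,
  `sdlog = (log q3 − log q1) / (2 z_{0.75})`. A lognormal is log-symmetric,
  so when the published quartiles are slightly asymmetric in log space
  (0.9 and 2.2 around a median of 1.4) the fit preserves the median and the
  log-quartile spread exactly and splits the residual asymmetry between the
  two quartiles (about 0.01 on each); the tests assert exactly this.
* **Independence given class.** No inter-feature correlations are
  published, so features are sampled independently within class. A
  Gaussian-copula hook (`copula_cor` in `cohort_config()`) exists for
  sensitivity analyses but is off by default.
* **Truncation.** Physically positive quantities (BMI, tumor size, the
  metabolite ratio) are truncated at zero by redrawing; a support with no
  probability mass errors out after a bounded number of rounds rather than
  looping forever.
* **Dual encoding.** ASA score (1–3) and hypertension grade (0–2) carry a
  `dual` flag: the benchmark runs them both as numeric and as factor
  columns (`cohort_model_frame(encoding =)`), mirroring the two dataset
  variants the study compared. The BRF stage uses the all-numeric frame.
* **The merged fluid row.** The published table reports crystal and
  colloid fluid use as one row while the attribute list treats them as two
  predictors; both synthetic features therefore share that row's
  class-conditional probabilities. This is a documented data limitation,
  not a modeling claim.
* **No missing data** are generated; the study table is complete.

What passing tests on these cohorts *do* show: the algorithms are correct
(parameter recovery within 3 standard errors at n = 10⁵, exact balance,
leakage-free splits, deterministic replay). What they *do not* show:
real-data predictive performance. The synthetic cohort has the published
marginal effect sizes but none of the real correlation structure, so
benchmark and BRF numbers on it are pipeline diagnostics, not clinical
estimates — and with these modest marginal effects the held-out AUC lands
around 0.65–0.80 depending on seed. One visible consequence: Relief-F on
the synthetic cohort ranks several binary comorbidity/preparation features
(whose published class proportions genuinely differ) above the continuous
features, so the selected subset differs from the published one. That is a
property of summary-statistics emulation, not a defect of the scorer.

## Relief-F

`relief_f_weights()` implements the multi-class Relief-F weight update: for
each reference instance, the k nearest same-class neighbors (hits) pull a
feature's weight down by the per-feature distance contribution and the k
nearest neighbors of each other class (misses) push it up, weighted by the
prior odds P(C)/(1 − P(class of R)). Distances are Manhattan sums of
per-feature `relief_diff()` contributions — 0/1 for nominal features,
|a − b| / range for numeric ones — so every contribution lies in [0, 1] and
accumulated weights normalized by m·k lie in [−1, 1].

Parameters: `m = "all"` (every row used as a reference; removes sampling
noise at this data scale) and `k = 10` neighbors, capped at one less than
the smallest class (an explicit error if capping is disabled). A constant
feature is guarded by `range_epsilon` and scores exactly zero.
Nearest-neighbor ties are broken by a seeded shuffle, so results are
deterministic given the seed and row-order invariant when there are no
ties.

The published 18-attribute weight table sits on a very different scale
(large negative numbers, presumably an unnormalized accumulation whose
m/k/normalization were not reported) and is therefore shipped as a fixture
and used as an *input*: `select_above(w, -24)` reproduces the published
10-feature retention and `top_k(w, 5)` the Relief-F block of the consensus.
The weight function reports both the normalized weight and the raw
accumulated sum so either scale can be compared.

## Validation schemes and the benchmark

`default_schemes()` is the nine-cell validation grid: hold-out 80/20,
70/30, 60/40; 5-, 10-, 15-fold cross-validation; bootstrap train multisets
of 50, 100, 200. Choices:

* **Hold-out rounding** is `floor(n · frac)` training rows — on 283
  patients at 60/40 this yields the 114-patient test set behind the
  published confusion matrix.
* **Stratification** defaults on for hold-out and CV (it reduces variance
  at 26% prevalence) with largest-remainder per-stratum allocation; a
  stratum too small to appear on both sides degrades, with a warning, to
  unconstrained allocation.
* **Bootstrap disjointness.** The bootstrap family draws the train
  multiset with replacement and tests only on rows *never* drawn into it
  (subsampled to at most the subset size), the interpretation that
  guarantees train/test disjointness; 10 repetitions per scheme.
* **Baselines are delegated**, not reimplemented: logistic regression
  (`glm`), naive Bayes (`e1071`), Gini and information-gain `rpart` trees
  (the latter standing in for C4.5/C5.0), gradient-boosted trees
  (`xgboost`, standing in for boosted C5.0) and `randomForest`. The
  C4.5/C5.0-family approximations are labeled as such in
  `default_classifiers()`.
* Cell AUC over a multi-part plan is the unweighted mean of per-part AUCs;
  a single-class test part has no AUC and is excluded from that mean. A
  classifier failure marks its cell failed with the diagnostic and the
  grid continues.

## The balanced random forest

The core algorithm, for a binary imbalanced outcome:

1. split the training rows into majority (no IHD) and minority (IHD)
   subsets;
2. for i = 1 … m, draw n rows with replacement from *each* class — a
   class-balanced bootstrap — and train random forest RF_i on those 2n
   rows;
3. classify by sign voting: BRF(x) = sgn Σᵢ RF_i(x), with each RF_i voting
   +1 (minority) or −1 (majority).

Implementation decisions:

* **One global held-out test set.** A literal per-iteration "test on the
  complement of each resample" would let every row be tested by voters
  that trained on it. The package instead holds out the evaluation set
  before training (stage 4 of the analysis uses the stratified 60/40
  split) and uses the per-forest complements only for out-of-bag
  diagnostics and permutation importance.
* **Defaults.** `n = "auto"` (the training minority size, classic balanced
  bagging), `m = 21` voters (odd, so hard-vote ties are rare),
  100 trees per forest, `mtry = sqrt(p)`. None of these are identified by
  the study; all are configurable.
* **Tie rule.** A zero vote sum (possible for even m) resolves to the
  minority class — conservative toward the clinically dangerous outcome —
  and is unit-tested.
* **Hard votes vs scores.** The sign vote reads the pseudocode literally
  (each RF_i contributes ±1). For ROC construction `predict_score()`
  separately averages the forests' minority-class probabilities.
* Per-forest seeds are derived deterministically from the config seed;
  audit multisets of every resample are retained and asserted exactly
  balanced in the tests.

The property the design targets — and the suite checks over 25 seeded
283-patient cohorts at the study's 1:2.82 imbalance — is that the balanced
ensemble recalls more of the minority class than a single plain forest
trained on the unbalanced data.

## Model assessment

The study's orientation convention is preserved: **positive means y = 0,
the normal (no-IHD) patients**. `confusion()` embeds that meaning in the
object so it cannot be silently inverted, and an explicit
`positive_label = 1` flips it. `metric_set()` computes accuracy, TPR
(sensitivity/recall), TNR (specificity), PPV (precision), FPR and f1
exactly from their count formulas; any zero denominator yields `NA` listed
in the `undefined` attribute, never a silent zero. Metrics are reported at
full precision; the tables in `results/` round to 4 decimals for display.

`roc_curve()` sweeps one threshold per distinct score (ties collapse into
a single diagonal step) with exact (0,0)/(1,1) endpoints; `auc()` is the
trapezoid, which equals the Mann–Whitney probability with ties counted one
half — asserted against an O(n²) pairwise oracle on random instances up to
n = 12, and against `pROC` as an independent reference. `metric_ci()` is a
percentile bootstrap over test rows (2000 replicates by default;
single-class resamples are skipped, and more than 20% skips is an error).
The bootstrap is the package's own choice: the study prints a 95% interval
without stating a method, and does not even disambiguate which quantity it
covers, so that printed interval is not a recomputation target.

## Variable importance and consensus

* **MDA** (`mda()`): per base forest, accuracy on its out-of-bag rows
  minus mean accuracy after permuting one feature column (10 seeded
  permutations by default), averaged over forests; reported in percentage
  points. Permuting a constant column gives exactly zero, and a pure-noise
  feature is centred at zero over repeated simulation.
* **MDG** (`mdg()`): authored tree routing over each forest's recorded
  splits — the in-bag rows (bootstrap counts as weights) are pushed
  through every tree and each split contributes its node-weighted Gini
  decrease, with node weight the fraction of in-bag rows reaching the
  node. On a perfectly separating stump with balanced classes this is
  exactly 0.5 (impurity 0.5 to 0 at weight 1); feature sums conserve each
  tree's total impurity decrease; and the ranking agrees with
  `randomForest`'s own Gini importance, which the tests use as an
  independent cross-check.
* **Consensus** (`consensus_select()`): take the top k = 5 of each of the
  three lists (MDA, MDG, Relief-F) and keep features present in at least
  `min_lists = 2`. The study's prose says "more than two", but its own
  published result keeps features appearing in exactly two of the three
  top-5 lists, so ≥ 2 is the default (the literal ≥ 3 reading is one
  argument away). k = 5 matches the three published score thresholds, each
  of which cuts its list at five entries. On the shipped published score
  tables this rule returns exactly {bmi, size, prevma, ctvalue, age}.

## Numerical and testing choices

* One global seed is fanned out per stage (and per benchmark cell) by a
  small string-hash below 2³¹, so every stochastic call is reproducible
  from a single integer and the pipeline's seed ledger records each
  stage's derived seed.
* Degenerate inputs fail loudly: single-class cohorts, mis-ordered
  quantiles, k larger than the smallest class, empty bootstrap pools,
  zero-mass truncation supports and schema mismatches all raise named
  errors; empty classes in summaries are flagged `absent`.
* Test problem sizes are chosen to make each property sharp but cheap:
  parameter recovery at n = 10⁵ over three seeds, Relief-F signal
  detection over 100 seeded 150-patient cohorts, the BRF recall comparison
  over 25 seeded 283-patient cohorts, AUC/bootstrap-coverage studies at
  n ≈ 100. The whole suite runs in well under a minute.

## Known limitations

* Synthetic cohorts carry no inter-feature correlation (unless supplied
  via the copula hook), no missingness, and only the published marginal
  effects; absolute performance numbers on them do not transfer to real
  patients.
* The published Relief-F weight scale is not reproducible from the
  published information; orderings and retention cuts are.
* The published MDA/MDG scores cannot be recomputed without the clinical
  data and are used only as consensus inputs.
* C5.0 and its boosted variant are approximated by information-gain
  `rpart` and `xgboost`; no claim of C5.0-exact behavior is made.
* The BRF is binary by construction (sign voting); no multiclass
  extension, cost-sensitive weighting or synthetic-oversampling (SMOTE)
  variants are provided.
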