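---
title: "Simulating and evaluating consensus-validated COPD triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and evaluating consensus-validated COPD triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patients with chronic obstructive pulmonary disease (COPD) face a daily risk
of exacerbation — an acute worsening of dyspnea, cough and/or sputum beyond
day-to-day variation. At home they must decide between four ordinal actions:
do nothing (*Ok*), continue treatment and recheck in a day or two (*Plan*),
call the doctor (*Doc*), or go to the emergency room (*ER*). A classifier
can be trained to make this call from symptoms, vitals and patient history,
with the consensus of a physician panel as the reference standard. Because
no outpatient triage registry exists, both the training cases and (in this
package) the panel itself are simulated. `copdtriage` implements that whole
loop — case simulation, panel labeling, consensus, model training and
selection, safety-aware evaluation, and a panel-size robustness analysis —
as testable, seed-reproducible code.

## Case simulation

**Schema.** `copd_schema()` declares 31 collected variables — patient
profile (age, weight, height, gender, GOLD stage, baseline MMRC dyspnea,
recent exacerbations, living situation, smoking, oxygen use, assisted
daily activity), seven comorbidities, nine symptoms, four current vitals —
plus four baseline vitals used as anchors for delta features. Every
variable admits an `unknown` response except age, weight, height, gender,
baseline dyspnea and the symptom questions, so models can be trained on
cases with missing data. FEV1 is carried as percent of predicted, the
scale on which its printed feature bins live.

**Stage 1: D-optimal profile design.** Profiles and baseline vitals are
chosen by maximizing the D-criterion `det(X'X)` of a linear main-effects
model matrix over a random candidate set, via a best-swap Fedorov exchange
(`federov_exchange()`) with random restarts. The exchange uses the
classical variance-function delta, so a pass costs a single matrix
inverse; the criterion reported is always the exact log-determinant. The
default design has 100 points, which is comfortably above the 22 coded
parameters. Exhaustive search over all subsets verifies global optimality
on small candidate sets in the test suite; at realistic sizes a local
optimum over restarts is the standard compromise.

**Stage 2: Monte Carlo completion.** Comorbidities, symptoms and current
vitals are filled in by a Gaussian copula: latent draws over a configured
correlation matrix mapped through per-variable marginals
(`default_marginals()`, `default_correlation()`). Defaults encode a
plausible COPD population — e.g. hypertension prevalence 55%, symptom
levels positively intercorrelated (ρ = 0.3), current O2 saturation and
FEV1 shifting downward from baseline and negatively correlated with the
symptom block. These are *configuration, not estimates*: the package makes
the statistical structure (correlated severity) explicit and swappable
rather than claiming epidemiologic fidelity. A non-positive-semidefinite
correlation override is repaired by eigenvalue clipping with a warning.
Unknown responses are injected at a configurable rate (default 5%) into
unknown-admitting variables only.

The default cohort is 2,501 cases — the 100 design profiles, replicated by
uniform resampling to the full size — with 101 cases randomly held out for
validation and 2,400 used for training.

## Feature encoding

`encode_features()` emits the model feature space: numeric age, height
and BMI (imperial, from weight and height); one-hot level indicators
(yes/no variables contribute their *yes* indicator; multi-level variables
all levels, plus an unknown indicator where admissible); half-open
right-closed bins for current vitals (O2 saturation cut at
85/87/89/91/93, heart rate at 100/110/120 with an open top bin, FEV1 in
decades); FEV1 percent-change bins (−100/−15/−5/0/10, so an unchanged
FEV1 falls in `(-5, 0]`); the combined `sputum(col+vol)` feature counting
worsened sputum signs; and the O2-saturation-change block, which is
left-closed `[a, b)` as its printed names indicate and active only when
baseline saturation is below 93% (a desaturation from an already-low
baseline is the clinically alarming pattern). Every binned variable's
indicators, including its unknown flag (and, for the gated block, a
baseline ≥ 93 flag), sum to one — a property the tests enforce — and delta
features are defined only when both current and baseline values are known.

## The synthetic physician panel

Each rater is a `rater_policy()`: a linear severity score over encoded
features, Gaussian latent noise, three thresholds mapping the score to the
four triage categories, and a separate weighted rule for the binary
exacerbation call. Confidence is a saturating function of the distance
between score and nearest threshold, recorded but deliberately unused by
consensus. `default_panel()` builds nine raters around shared severity
weights, calibrating thresholds on the empirical score distribution at
target shares of roughly 25/30/25/20 percent across Ok/Plan/Doc/ER, then
jittering weights and thresholds per rater (log-normal factor 0.15, and
latent noise at 15% of the score SD by default). Two deliberate outliers
reproduce the heterogeneity real panels show: rater 2 is an extreme
over-triager sending roughly 63% of cases to the ER, and rater 3 an
under-triager calling roughly 32% of cases fine — both flagged by the
2-standard-deviation rule in `label_distributions()`.

This additive-severity family is the simplest generative model that (a)
mirrors the 1–5 severity ratings physicians actually provide, (b) spans
the observed heterogeneity, and (c) gives a *known ground truth* for
recovery experiments: with noise set to zero the panel is a deterministic
threshold rule that a classifier should re-learn almost perfectly. What it
does not emulate: case-order effects, fatigue, non-additive clinical
gestalt, or systematic disagreement about specific clinical syndromes.
Passing recovery tests therefore show the harness works, not that any
model would match real physicians.

## Consensus

`majority_vote()` takes the modal category; ties resolve to the *higher*
(more conservative) category — for exacerbation, "yes" is the conservative
side. `consensus_labels()` supports the three membership scenarios used in
evaluation: physicians only, physicians plus the algorithm's votes, and
leave-self-out (the consensus scored against a member excludes that
member's own votes; whether the algorithm's votes stay in the pool is
controlled by supplying or omitting `algo_votes`, since either reading is
defensible). Votes are unweighted.

## Models and selection

`train_and_tune()` runs an exhaustive grid search scored by stratified
5-fold cross-validated accuracy and refits the winner. Families: gradient
boosted trees (xgboost), one-vs-rest logistic regression, linear /
polynomial / Gaussian-kernel SVMs, random forest, extremely randomized
trees, naive Bayes, and k-nearest neighbours. Triage is treated as plain
multiclass (matching the one-vs-rest logistic description); ordinal-aware
losses are out of scope. Features are standardized for the
scale-sensitive families; zero-variance columns are dropped. The logistic
family uses a small ridge penalty (λ on a grid, default 10⁻³–10⁻²): the
full one-hot encoding is rank-deficient and noiseless synthetic labels are
separable, so unpenalized maximum likelihood is undefined exactly where
this package needs coefficients most — the penalty keeps every
coefficient finite and comparable. `select_top_models()` scores the
fitted records on the validation consensus and returns the per-family
best and overall top two — the study's protocol, which knowingly reuses
the validation set for selection; a stricter protocol would nest another
held-out fold, and nothing in the package prevents doing so.

Two importance schemes are implemented rather than taken from library
accessors, since their definitions are part of the reimplemented surface:
for gradient boosting, each feature's expected *fraction of samples* it
contributes to — per tree, the cover of its split nodes over the root
cover — averaged across all trees and normalized to sum to one; for
logistic regression, each feature's rank by absolute coefficient within
each one-vs-rest binary model, averaged across the four models (one for
exacerbation).

## Evaluation

All statistics live on the consensus-vs-prediction confusion matrix with
rows ordered Ok < Plan < Doc < ER, so everything below the diagonal is
under-triage. `triage_metrics()` computes classification accuracy;
emergency one-vs-rest sensitivity, specificity, PPV and NPV (ER as
positive class); the upper-triangular proximity `UTP = 1 − LT/n` (the
denominator generalizes the validation size to `n`); and the share of
errors greater than one ordinal category. `medical_attention_metrics()`
collapses {Ok, Plan} vs {Doc, ER} and recomputes the 2×2 statistics —
medical attention meaning the case calls for physician assistance or
emergency care. Zero-denominator metrics are reported as missing, never
coerced. `safety_summary()` breaks misclassifications into under- and
over-triage. For a binary task the UTP definition degenerates (a 2×2
matrix has a single lower-triangle cell), which is why the package leaves
binary UTP to the caller's interpretation rather than targeting any
particular printed value.

Every formula is checked against an independent per-case tally oracle on
a thousand random label vectors, and the worked 101-case matrices
described in the results narrative reproduce their printed statistics
(88.1% accuracy, UTP 96.0, no greater-than-one-category errors; 86.25%
attention sensitivity from 11 misses in 80).

## Panel-size robustness

`convergence_curve()` asks how many raters a stable consensus needs: for
every base panel of size *s* (from 5 up), for *every* size-*s* subset of
the member pool, it computes the consensus, then the percentage of cases
whose consensus changes as each non-member is added, averaged over added
members; the mean/max/min over subsets give one convergence point per
size. Enumeration is exhaustive — with at most ten members this is cheap —
so the curve has no sampling noise at all. The algorithm's votes can be
appended to the pool to study the panel-plus-algorithm variant.

## Reproducibility and problem sizes

Every stochastic stage takes a seed, and the pipeline derives all stage
seeds from one global seed; two runs with the same configuration are
bit-identical. The shipped test suite exercises compact cohorts (a
250-case cohort for module tests) and one full-scale recovery experiment
(2,501 cases, 100-point design, 2,400/101 split), the sizes the package
defaults to; `scripts/acceptance.R` re-runs the full-scale experiments
from scratch.

## Known limitations

* Marginals and correlations are plausible defaults, not fitted to
  epidemiologic data; conclusions about *real* triage behavior require
  real labels (the S1-style reader ingests such spreadsheets when
  available).
* Physician judgment is additive and memoryless; inter-rater correlation
  beyond shared weights (e.g. shared training biases on specific
  syndromes) is not modeled.
* Triage models are plain multiclass; the ordinal structure enters only
  through evaluation, not the loss.
* The profile-replication rule (uniform resampling of design points up to
  the cohort size) is one defensible reading of "redesigning" a larger
  set; alternatives (fresh larger designs) are a one-line configuration
  change.
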