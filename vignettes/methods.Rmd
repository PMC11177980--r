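---
title: "Methods: uncertainty-aware selective classification for prehospital ACS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uncertainty-aware selective classification for prehospital ACS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acsselect)
```

## Scope and model

`acsselect` implements a selective-classification pipeline for acute
coronary syndrome (ACS) prediction from 23 prehospital covariates: age and
sex, ten medical-history binaries, eight symptom binaries, and three ECG
interpretations (ST elevation, ST depression, T-wave inversion), each a
length-11 binary vector over ECG leads. The leads are unnamed in the
source material, so columns are labelled positionally `L01..L11`.

The classifier is an ensemble of `M` gradient-boosted tree models whose
members differ only in their random seed and row subsampling, making them
exchangeable draws from an approximate posterior over model parameters.
The posterior predictive distribution for a case is the member mean; its
Shannon entropy is the *total uncertainty*, which splits into *data*
uncertainty (the mean member entropy — irreducible outcome randomness)
and *model* uncertainty (their difference, a mutual information — member
disagreement, high for inputs unlike the training data). The abstention
rule thresholds total uncertainty at the empirical 0.8 quantile of a
held-out validation split, so that close to 80% of exchangeable test
cases are retained.

The ensemble members are fitted with `xgboost` (binary logistic
objective). This satisfies the pipeline's contract — `M` exchangeable
probabilistic members — without reproducing any particular boosting
library's posterior-sampling internals; the uncertainty, selective and
evaluation layers are agnostic to the member implementation.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `n_members` (M) | 10 | ensemble size; M = 1 degenerates to single-model predictive entropy (model uncertainty exactly 0) |
| `learning_rate`, `depth`, `subsample` grid | {0.01, 0.1, 1.0} × {1, 3, 6, 10} × {0.25, 0.5, 0.75} | the 36-point search space; selection by validation AUROC, ties broken toward smaller depth then smaller learning rate for reproducibility |
| `iterations` | 1000 | boosting rounds per member |
| `class_weight_mode` | inverse frequency | ACS prevalence is ~20%; weights are recomputed from each fold's training labels and normalised to average 1 |
| `coverage_target` | 0.8 | validation-quantile level of the abstention cutoff; coverage below ~80% was judged clinically unhelpful in the setting this design targets |
| decision `threshold` | 0.5 | on the class-weighted ensemble-mean P(ACS); the source protocol never states its threshold, so the conventional value is fixed and exposed as an argument |
| `numeric_fill`, `binary_fill` | −1, 0 | constant imputation; only "a constant" is specified upstream, so the fill is configurable |

Uncertainties are reported in nats (natural-log entropy; `0·log 0 := 0`).
The entropy base is a free choice — quantile-based cutoffs are invariant
to it — but reported uncertainty values are base-dependent, so nats are
used consistently.

## The synthetic cohort generator

The real registry data behind this design are private, so every stage is
exercised on synthetic cohorts built to have the statistical structure
the analysis assumes:

* **Marginals.** Binary covariates are Bernoulli with the published
  internal/external cohort rates (e.g. hypertension 53% vs 71% — the
  planted distribution shift); age is normal (mean 61/60, SD 15.5 years)
  truncated at 21, the enrolment threshold. The published age spread of
  "±31" is interpreted as two standard deviations; whether it is an SD,
  2 SD or an IQR-like spread is not stated.
* **ECG vectors.** The published tables summarise each interpretation as
  a single rate despite the per-lead type; the generator reads it as
  any-lead positivity, then draws the number of positive leads from a
  truncated geometric on 1..11 (p = 0.45) and places them uniformly. No
  per-lead information exists to do better.
* **Outcome.** A latent linear risk score (per-covariate log-odds, ECG
  contributing per positive lead) feeds a logistic link whose intercept
  is calibrated by bisection on a 200,000-score pilot sample so marginal
  ACS prevalence hits 20%. Subtypes are drawn as (STEMI, NSTEMI, UA) =
  (0.65, 0.20, 0.15) given ACS, reproducing NSTE-ACS 7% and UA 3%. The
  published subtype marginals sum to 21% against 20% ACS (rounding), so
  STEMI lands at 13% rather than 14%; the three mutually consistent
  prevalences were kept.
* **Effect sizes.** Defaults put the strongest weight on ST-elevation
  leads, moderate weight on ST depression, chest pain, diaphoresis and
  the history covariates, and none on the non-specific "Other" symptom,
  chosen once so that a default-size trained ensemble reaches an external
  AUROC in the mid-to-high 0.8s — the performance regime the protocol is
  meant to be studied in. This is a modelling choice, not an estimate.
* **Missingness.** Completely at random at patient level (rate 1.5%,
  below the documented 2% bound), blanking one or two covariates (a hit
  on an ECG interpretation blanks its whole vector). The real missingness
  mechanism is uncharacterised.
* **Troponin.** An ordinal band {0,1,2} drawn conditionally on ACS status
  — informative by construction — used only by the HEART comparator,
  since troponin is generally unavailable prehospital.

What passing tests on these cohorts does **not** show: real covariate
correlation structure (covariates are independent given the latent
score), real ECG lead topography, calibration drift of real models, or
clinical performance levels. The pipeline's *behaviour* (coverage
control, uncertainty decomposition, leakage-free protocol, ordering of
ablations) is what the synthetic studies validate.

## Evaluation protocol

Five-fold stratified cross-validation on the internal cohort: per fold,
20% is the internal test set; 10% of the remaining training portion
(stratified) becomes the validation split used for the grid search and
the cutoff; the model trains on the rest. The entire external cohort is
scored by every fold's model. That yields five performance samples per
metric; reports give mean and twice the *standard error* of the five
fold values (the "±2σ" convention of the source protocol; twice the SD is
available via `aggregate_report(..., dispersion = "sd")`). Undefined
ratios (empty denominators after filtering) are excluded from aggregation
with a warning, never imputed as zero. A leakage assertion — fold sets
partition the internal cohort, the external cohort appears nowhere in
fitting or cutoff estimation — runs every fold.

The NSTE-ACS task relabels STEMI cases as negative and fits a fresh model
rather than reusing ACS scores, consistent with the separate
hyperparameter search the source protocol implies.

## Numerical and design choices

* **Quantile convention.** Inverse-ECDF lower quantile (`type = 1`): the
  cutoff is the smallest observed validation value whose ECDF reaches the
  target, so validation coverage is the smallest achievable fraction at
  or above the target. Equality at the cutoff retains the case (the
  exclusion rule is strictly "greater than").
* **Coverage target 1.** Taken to mean "no abstention": with the cutoff
  at the validation maximum, test cases can still exceed it, so the
  protocol disables filtering entirely at target 1 to keep selective and
  non-selective results identical.
* **Ties in the risk–coverage sweep** break by original case order, and
  grid-search ties break toward simpler models, so all outputs are pure
  functions of (inputs, seed).
* **Decomposition tolerance.** Model uncertainty below 0 by at most 1e−9
  is clipped (floating point); larger violations raise an error, since
  Jensen's inequality forbids them.
* **Grid search cost.** Candidates are scored with a single member and
  the winner refit at full M. A full-M search multiplies fitting cost by
  36 with no change in the selection rule's contract; the single-member
  AUROC is an unbiased (noisier) ranking signal. `grid_members` exposes
  the trade-off.
* **HEAR/HEART mapping.** The source protocol delegates component
  definitions to the score literature and does not state its mapping, so
  a documented proxy table ships as an editable YAML asset: age 0/1/2 at
  <45 / 45–64 / ≥65; risk factors 0/1/2 at 0 / 1–2 / ≥3 with prior
  MI/PCI/CABG/CAD forcing 2; ECG 2 for any ST change, 1 for isolated
  T-wave inversion; history proxied from the symptom pattern (chest pain
  ± autonomic symptoms). Comparisons against these scores are therefore
  qualitative (direction of correlation), not numeric reproductions. The
  `hear_matched` covariate subset (age, sex, chest pain, any-lead ECG
  summaries, nine risk-factor history binaries) is the information the
  HEAR score consumes.

## Problem sizes

The shipped tests and analysis drivers run the study at the design sizes
(internal n = 1756, external n = 1127, M = 10, 5 folds, 20 replicate
seeds for the end-to-end checks) but with 40–150 boosting rounds and a
reduced grid of published candidate values — sizes at which the fitted
ensembles already reach the intended AUROC regime and the full replicate
study completes in minutes on one CPU. The package defaults
(`iterations = 1000`, the 36-point grid) reproduce the full-size search.
Generator calibration checks use n = 20,000 draws against 3-binomial-SD
tolerances.

## Known limitations

* Conditional independence of covariates given the latent score is a
  stand-in for the unknown real correlation structure.
* The decision threshold (0.5) and the grid-search objective (validation
  AUROC) are choices the source protocol leaves unstated; sensitivity /
  specificity trade-offs shift with the threshold.
* Model-vs-data uncertainty is computed and exported but not used for
  differentiated clinical actions; only total uncertainty drives
  abstention.
* Why the ECG vectors have 11 (not 12) leads is unexplained upstream;
  the schema simply preserves the published type.
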