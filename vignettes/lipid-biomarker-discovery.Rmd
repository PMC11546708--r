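---
title: "Methods: resampled lipid biomarker discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resampled lipid biomarker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidscreen)
```

# The problem

Untargeted LC-MS/MS lipidomics of blood yields a table of relative
concentrations for a few hundred lipid species per subject. Given two
clinical groups (here: healthy controls versus early-stage breast
cancer), the task is to find a small panel of lipids whose joint
profile separates the groups, and to estimate how well a classifier
built on that panel will generalize — without fooling ourselves through
feature-selection leakage or a lucky train/test split.

`lipidscreen` implements two complementary workflows over one data
container (the `feature_table`: samples x lipids values plus sample and
lipid metadata):

1. **A differential-abundance panel** — per-lipid linear models on log2
   concentrations, a fold-change plus false-discovery-rate filter with
   isomer inclusion, stepwise m/z restriction, and a leave-one-out
   cross-validated (LOOCV) logistic score with an accuracy-optimal
   threshold.
2. **A resampling discovery engine** — repeated leave-group-out
   cross-validation (LGOCV, 80/20 splits) where *within every split*
   the Boruta all-relevant selector is run on the training data alone,
   a suite of classifiers is tuned by nested random search, and the
   held-out fifth is scored by a majority-vote ensemble. Lipids are
   ranked by *selection frequency* (the fraction of splits in which
   Boruta confirmed them), the top-k prefix becomes the signature, and
   a final LGOCV pass with the signature and hyperparameters frozen
   yields the reported performance distribution, certainty
   stratification, and signature-size sensitivity analysis.

# Statistical model and assumptions

## Preprocessing

Relative quantitation divides each lipid's peak area by the internal
standard (ISTD) of its lipid class in the same sample; concentrations
are subsequently log2-transformed (with an optional pseudo-count for
retained zeros). QC reproducibility is summarized as the
coefficient of variation (CV%, SD/mean on the *linear* scale — a CV on
log values is not a CV) over pooled-reference replicates, flagged at
the conventional 30% bound.

Batch normalization composes two multiplicative corrections on the
linear scale: per-sample median scaling (every sample's median lipid
concentration is brought to the global median of sample medians) and
per-(lipid, batch) internal reference scaling (IRS), where the QC pool
replicates present in every batch act as the internal reference and
each lipid is scaled by the geometric mean of its reference means
across batches divided by its reference mean in that batch. The IRS
step is computed on the median-scaled table, so reference means are
*exactly* equal across batches afterwards. The two steps do not commute
exactly because the median is nonlinear; we apply each once, in that
order. Iterating them does not converge to a fixed point (the
alternation settles into a small limit cycle), so re-normalizing an
already-normalized table changes values by a small residual (of order
1e-2 relative at the default study size) rather than zero — the
property tests assert exact idempotence only in the single-batch case,
where it genuinely holds, and contraction otherwise.

## Differential abundance

Each lipid is fit with `log2 conc ~ group + cohort` (cohort dropped if
constant); the group effect is tested by the partial F test, which for
two groups without covariates reduces to the squared pooled t test.
Fold change is reported as `2^(group coefficient)` — the ratio of group
geometric means on the linear scale — and p-values are adjusted by
Benjamini–Hochberg. A mixed-model variant (batch as a random intercept,
REML via `nlme`) is available; the fixed-effects model is the default
because the synthetic designs keep groups balanced within batch, where
both estimators coincide asymptotically.

The panel filter requires `q < 0.05` and fold change above 1.2 *in
either direction* (`max(FC, 1/FC) > 1.2`): depleted lipids are as
informative as enriched ones, and volcano plots of real cohorts show
both tails. Isomer inclusion then adds every isomer-group mate of a
selected lipid — co-eluting isomers share m/z and annotation and cannot
be quantified independently, so a panel that includes one must carry
its mates. Stepwise m/z restriction is forward-only on AIC over m/z
*groups* (a group enters as the set of its member lipids), reflecting
that a mass-spectrometric assay measures m/z channels, not individual
isomers. On separation the step falls back to a ridge-penalized
deviance with the same 2k penalty, with a warning.

The LOOCV logistic score deliberately reproduces a known weakness of
the reference workflow: the decision threshold is chosen to maximize
accuracy *on the same LOOCV scores it is then evaluated on*. This
in-sample threshold optimization is flagged here rather than fixed,
because the workflow exists to be compared against the resampling
engine that supersedes it.

## Boruta

The selector is implemented from scratch. Each iteration appends one
*shadow* per active feature — an independent row permutation of that
feature, preserving its marginal distribution while destroying any
association with the outcome — grows a random forest on the augmented
matrix, and scores a *hit* for every real feature whose importance
strictly exceeds the maximum shadow importance. After a burn-in of 5
iterations, each feature's hit count is tested against
Binomial(k, 1/2): the upper tail confirms, the lower tail rejects, both
at `alpha = 0.01` Bonferroni-adjusted by the *initial* feature count
(the conservative reading; the adjustment factor is not recomputed as
features drop out). Rejected features leave the forest; undecided
features end tentative, and only confirmed features feed the
classifiers — "consistently important" is read strictly.

Importance defaults to out-of-bag permutation importance scaled by its
standard error, with Gini (impurity) importance as the fast profile.
The forests come from `ranger` with a single thread, so a fixed seed
gives bit-identical selections.

## Ensemble engine

Splits are stratified by class: the held-out set has
`round(0.2 * n)` samples and class proportions within one sample of the
cohort's. Per split, each classifier's hyperparameters are tuned by
random search (`tune_len` candidates, identical nested splits for all
candidates, ties to the first drawn) over nested 80/20 LGOCV of the
training set, then refit on the whole training split. The default
suite covers eight families — regularized logistic regression, linear
discriminant analysis, radial and polynomial SVMs, random forest,
gradient boosting, k-nearest neighbours, Gaussian naive Bayes, and a
seed-averaged small neural network — nine fitted models in total. The
registry is pluggable; the reference protocol's 18-model roster
(including Distance Weighted Discrimination and SIMCA) is intentionally
not reproduced model-for-model, since the ensemble contract (votes at a
0.5 score threshold, majority rule) is what the method depends on.

Ensemble predictions are majority votes with ties called cancer — the
clinically conservative direction. The vote fraction doubles as a
continuous score for ROC work; per-iteration ROC curves are averaged
vertically on a fixed false-positive-rate grid and the AUC is the mean
of per-iteration Mann–Whitney AUCs (ties one half). Certainty bins
model agreement: `high` is unanimity, `medium` at least 80%, `low`
below.

Final hyperparameters are frozen per classifier by the *median
best-rank run* rule: rank classifiers within each iteration by held-out
accuracy (ties share the minimum rank), find the best rank the
classifier ever achieved, and among those iterations take the one with
the median accuracy — lower median for even counts, first index on
exact ties — so the frozen configuration comes neither from a
suspiciously easy split nor from a hopeless one.

The signature-size sensitivity analysis re-runs the frozen evaluation
for top-k prefixes (default k = 14..30) and picks the smallest k whose
median accuracy is within 0.5 percentage points of the best median:
prefer the smallest panel that costs nothing.

# The synthetic cohort generator

Because the motivating study deposits no raw data, every stage is
exercised on synthetic cohorts with planted ground truth. The generator
draws, per class, a one-factor Gaussian model on the log2 scale:
lipids of one class share a latent factor with correlation
`within_class_corr` (default 0.3 — real lipid classes co-regulate, but
no estimate of the magnitude is published, so this is a stated
assumption, not a fit), on top of per-lipid baselines centred at
class-level means. Cancer samples are shifted by `effect_log2fc` on the
informative subset. Per-(batch, lipid) multiplicative factors
(`batch_sd`, log2 SD, default 0.2) and per-sample-type technical noise
(EV noisier than plasma: 0.35 vs 0.15 log2 SD, emulating the observed
reproducibility gap) complete the measurement; plasma tables are scaled
up by `plasma_scale` (default 4). QC replicates are re-noised copies of
one pooled-reference profile injected into every batch, mirroring
reference-material QC practice, and groups are balanced within batch by
construction. Matched EV/plasma tables share all biology and batch
factors, differing only in scale and technical noise, which makes the
per-subject cross-matrix Pearson correlation high when biology
dominates noise — the qualitative pattern reported for real matched
samples.

The default design mirrors the study: 128 + 128 subjects, 454 lipids in
15 classes, 4 batches, 5 QC replicates per batch, 10 informative lipids
at one biological SD.

What the generator does *not* emulate: missing values and limit-of-
detection censoring, heavy-tailed and lipid-specific noise, run-order
drift within batch, class-imbalanced designs, correlated effect
directions within a pathway, and any relationship between m/z and
abundance. Passing the recovery tests therefore shows the pipeline's
machinery is sound under its stated model — not that real cohorts will
yield panels of any particular quality.

## Closed-form oracle

Under the generator's equal-covariance Gaussian model the Bayes rule is
linear and its AUC is `pnorm(Delta / sqrt(2))` with `Delta` the
Mahalanobis distance between group means; the block-diagonal class
structure makes this computable exactly (`analytic_bayes_auc`). The
engine's measured ensemble AUC is required (in the acceptance suite) to
land within 0.05 of this ceiling on strong-signal data and never to
exceed it meaningfully — a two-sided check that the machinery neither
loses signal nor manufactures it.

# Numerical and reproducibility choices

* All randomness flows from one root seed through named sub-streams
  (`substream_seed`), so any stage reproduces in isolation; forests and
  boosters run single-threaded with explicit seeds, making full
  pipeline runs byte-identical.
* Thresholds: the accuracy-optimal threshold scans midpoints between
  consecutive sorted unique scores plus sentinels, ties toward the
  smallest threshold (favouring sensitivity). Model votes use
  `score >= 0.5`.
* Degenerate inputs: constant lipids get `p = 1, FC = 1` with a
  warning; unstable logistic fits fall back to a small ridge penalty;
  an LGOCV iteration where Boruta confirms nothing falls back to all
  features and is flagged rather than aborting a long run; one-lipid
  signatures are zero-padded for the elastic-net fit.
* Serialization is plain text (CSV/JSON/NDJSON) at full double
  precision (`%.17g`); the run manifest records a config hash invariant
  to key order.

# Problem sizes used by the test and acceptance suites

The reference protocol's 2000 LGOCV iterations, 50 nested tuning
splits, and 500-tree/100-iteration Boruta are the package defaults.
The shipped test suites run the same code paths at sizes chosen for a
single-CPU workstation: 100 LGOCV iterations per recovery run (ten
seeded replicate runs), Boruta at 20 shadow iterations with 35-tree
depth-4 forests (mtry 55, Gini importance) inside each split, tuning
disabled (single default candidate) where tuning is not the property
under test, and a reduced classifier subset for the null-calibration
check. These profiles were fixed after benchmarking recovery quality on
pilot seeds disjoint from the test seeds. The binomial decision rule
adapts to the iteration count, so small profiles are statistically
valid, just less sensitive: at 20 iterations a feature needs 19 hits to
be confirmed at the Bonferroni-adjusted 0.01 level with 454 features.

# Known limitations

* The selection-frequency ranking breaks ties below the confirmed set
  by mean Boruta importance; at very small iteration counts many lipids
  tie at zero and the ranking tail is effectively alphabetical.
* The LOOCV panel workflow's threshold leakage is reproduced by design
  (see above); its reported accuracy is optimistic.
* The stepwise m/z restriction is greedy forward-only AIC; it will not
  recover a group that only helps jointly with another unadded group.
* Normalization assumes the QC pool is representative and present in
  every batch; single-reference batches estimate the IRS factor with
  that one sample's noise.
* `compare_panels` enumerates Venn regions; it is not a significance
  test of overlap.
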