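---
title: "Methods: hybrid resampling, F-score selection and GA-optimized stacking for imbalanced clinical data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid resampling, F-score selection and GA-optimized stacking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imbga)
```

## The problem

Clinical risk prediction for rare outcomes — the motivating case is
pregnancy-induced hypertension, where a cohort may contain a few dozen
affected pregnancies among thousands of controls — poses two coupled
difficulties. First, the class imbalance: a classifier trained on raw
data can reach high accuracy by never predicting the rare class, which
is clinically useless. Second, feature redundancy: routine obstetric
records carry dozens of correlated covariates, and models trained on all
of them waste their limited minority-class information on noise.

`imbga` addresses both with a three-stage method plus the evaluation
machinery around it:

1. **AMOM-DUMS hybrid resampling** — interpolation-based minority
   oversampling followed by iterated Tomek-link boundary cleaning;
2. **improved F-score feature selection** — a filter score tailored to
   imbalanced classes, wrapped in a cross-validated search over subset
   sizes;
3. **a GA-optimized stacked ensemble** — a two-layer stack whose
   first-layer subset, drawn from a pool of 10 heterogeneous
   classifiers, is chosen by a genetic algorithm with cross-validated
   AUC as fitness.

Throughout the package the label convention is fixed: `0` is the
minority class of interest, `1` the majority. The degree of imbalance is
summarized by the unbalanced ratio UR = n(majority) / n(minority); the
benchmark cohort shapes shipped as presets have URs of 4.324, 23.349,
16.049 and 50.86.

## Resampling

**Oversampling.** For a minority sample $u_i$, one of its $m$ nearest
minority neighbours $u_{ij}$ (Euclidean distance, computed on
normalized features) and $s \sim U(0,1)$, a synthetic sample
$u_{new} = u_i + s\,(u_{ij} - u_i)$ is added with label 0 until the
minority count reaches $\lceil \text{target\_ratio} \times
n_{maj}\rceil$. Defaults: $m = 5$ neighbours and `target_ratio = 1`
(full balance); the neighbour count follows the method's standard
setting and the target ratio is the conventional choice when the
stopping count is otherwise unspecified. Every synthetic point is by
construction a convex combination of two original minority points — the
test suite verifies this with a segment-membership oracle at tolerance
1e-9.

**Cleaning.** Interpolation can plant synthetic points inside the
majority region. The cleaning pass finds *Tomek links* — pairs of
opposite-class samples that are each other's single nearest neighbour —
and deletes the majority member of each pair (deleting the scarce
minority member would discard exactly the information the method is
trying to amplify; a `policy = "both"` option removes both). The scan
repeats until no link remains; ties in distance are broken by lowest
row index, and an all-identical input is rejected rather than looped
on. Deletion stops with a warning before a class would be emptied.

## Feature scores

For feature $i$ with overall mean $\bar U_i$, class means
$\bar U_i^{+}$ (majority) and $\bar U_i^{-}$ (minority), the standard
score is

$$F_i = \frac{(\bar U_i^{+}-\bar U_i)^2 + (\bar U_i^{-}-\bar U_i)^2}
{\tfrac{1}{n^{+}-1}\sum_a (U_{a,i}^{+}-\bar U_i^{+})^2 +
 \tfrac{1}{n^{-}-1}\sum_a (U_{a,i}^{-}-\bar U_i^{-})^2},$$

and the improved variant $F'_i$ keeps the same numerator but only the
majority-class variance in the denominator. With few minority samples
the minority variance estimate is noisy and can dominate the ratio; the
improved score removes that term, so a feature that separates the rare
class cleanly is not penalized for the rare class's own spread.
$F'_i \ge F_i$ whenever the dropped term is positive.

Numerical conventions: a globally constant feature scores 0; a feature
whose within-class variances vanish while the class means differ is a
degenerate perfect separator and is flagged `Inf` with a warning,
ranking above all finite scores. Rank ties are broken by original
column order. Both scores are exactly invariant to adding a constant to
a feature.

**The wrapper.** Features are ranked by $F'_i$; for each candidate
dimension $k$ the classifier (boosted stumps by default, logistic
regression for speed) is trained on the top-$k$ features under
stratified cross-validation and scored by mean held-out AUC; the best
$k$ wins, ties going to the smallest dimension. The all-features AUC is
recorded as the no-selection baseline. By default the ranking is
recomputed inside each training fold so the held-out fold never
informs the selection; `leaky_single_pass = TRUE` restores the simpler
rank-once flow.

## The stacked ensemble and the GA

**Pool.** The first layer draws from 10 heterogeneous learners: RBF
SVM, AdaBoost on decision stumps (implemented in-package, with staged
cumulative scores $D_z(u) = D_{z-1}(u) + \chi_z d_z(u)$ exposed for
testing), random forest, bagged trees, two gradient-boosting variants,
Gaussian naive Bayes, a Gaussian-process classifier, logistic
regression, and k-NN. Two members of the published panel (a Markov
random field and a deep confidence network) have no tabular-classifier
form to implement, so logistic regression and k-NN stand in; the pool
is fully configurable through `classifier_spec()`. The GP member uses a
deterministic median-distance RBF bandwidth and a subset-of-data cap
(400 training rows) since exact GP training is $O(n^3)$; its predictive
probabilities come from the standard probit-link Laplace treatment of
the underlying library. The SVM member emits logistic-squashed decision
margins, which are monotone in the class probability and fully
deterministic.

**Stacking.** Out-of-fold minority-class probabilities of each selected
member form the second-layer design matrix; the meta-learner is
logistic, $P(v = 1 \mid u) = 1/(1+e^{-w'^{T}u})$, fit with balanced
class weights and a ridge penalty whose strength is chosen by an
internal deterministic cross-validation. The class weights keep the
0.5 decision threshold meaningful when the out-of-fold labels are
heavily imbalanced; the ridge path guards against the meta-learner
overfitting the handful of minority rows its training matrix contains.
For deployment the selected first-layer members are refit on the full
training data.

**GA.** Chromosomes are length-10 bitstrings over the pool. Fitness is
the stack's cross-validated AUC, computed from a single precomputed
out-of-fold matrix so each chromosome costs only a meta-learner refit —
which is what makes exhaustive enumeration of all 1,023 subsets a
feasible reference. Selection is roulette-wheel
($P_i = fit_i / \sum_j fit_j$, accumulated-probability search),
recombination is multi-point block crossover, mutation flips each bit
independently, an all-zero chromosome is repaired by switching one
random bit on, and one elite individual survives unchanged per
generation, making the best-ever fitness non-decreasing. Defaults —
population 20, 15 generations, crossover rate 0.8 with 2 cut points,
mutation rate 0.05, elitism 1 — are conventional small-GA settings; the
search space has only 1,023 points, so the GA's job is to find the
optimum cheaply, and the test suite holds it to within 0.01 AUC of the
exhaustive answer. Accuracy-based fitness is available
(`fitness_metric = "accuracy"`), but AUC is the default because under
severe imbalance accuracy saturates for the all-negative predictor.

**Hyperparameters.** `grid_search()` enumerates the full Cartesian
product of a member's candidate values under stratified CV with a
deterministic first-in-enumeration-order tie-break.

## Leak-free cross-validation with oversampling

Oversampling the whole training set and then cross-validating on it is
subtly wrong: interpolated minority points land on both sides of a fold
boundary, so memorizing learners (k-NN, GP) look spuriously perfect and
any model selection built on those estimates — the wrapper's dimension
choice, the GA's chromosome choice — is steered toward memorization. In
development this showed up as fitness values of exactly 1.0. The
pipeline therefore resamples *inside* each training fold
(`resample` argument of `pool_oof_matrix()` and `wrapper_select()`):
fold assignment happens on the original rows, each training fold is
oversampled and cleaned independently, and held-out predictions are
always made on untouched real rows. Two lighter mitigations are also
exposed for custom workflows: `sampling_groups()` keeps each synthetic
point in the fold of its base sample, and `eval_mask` excludes
synthetic rows from metric evaluation.

## The synthetic generator

No clinical cohorts are distributed with the method, so every stage is
exercised on generated data whose statistical shape mirrors the
published cohort descriptions: two Gaussian clusters in an informative
subspace separated by `class_separation` pooled-SD units (the offset is
spread evenly over the informative axes so the Euclidean distance
between class means equals the configured value), redundant features
built as $\rho x_{parent} + \sqrt{1-\rho^2}\,\varepsilon$ so their
correlation with the parent is $\rho$, independent Gaussian noise
features, optional label flips, and an optional biomarker-style ratio
feature with a location-shifted denominator. The presets reproduce the
benchmark class counts exactly — `tableA` 392/1,695, `tableB` 86/2,008,
`tableC` 122/1,958, `pih1` 42/2,136 with 25 features (5 informative,
10 redundant, 10 noise) — with class separation 1.8, redundancy 0.7 and
no label noise, chosen once as a realistically hard operating point:
single-model test AUCs land in the 0.7–0.95 range, comparable to the
difficulty regime the method was designed for, and zero label noise
keeps the preset URs exact.

Problem sizes in the test suite are picked to keep the full run in
minutes on one core: sampler fixtures at $n \le 200$ (50 of them),
F-score oracle fixtures at $n \le 25$ (100 of them), the GA-vs-
exhaustive benchmark at $n = 400$ with the fast pool profile and 3
folds, and the pipeline comparison at the full `pih1` size (2,178 rows)
over 10 seeds with a reduced GA budget (population 12, 8 generations)
and 12 candidate dimensions.

## What the tests do and do not show

The directional claim — the full pipeline beats a single RBF-SVM
trained on the raw normalized data on recall, F-score and AUC in at
least 8 of 10 seeds at the `pih1` imbalance — holds on this generator.
Its complement is a structural limitation worth stating plainly: when
the *same* resampling and feature selection are handed to a single SVM,
the stacked ensemble matches but does not reliably beat it here. On a
Gaussian mixture an RBF-SVM is close to Bayes-optimal, all pool members
learn essentially the same boundary, and stacking has no error
diversity to exploit; the large ensemble-over-single-model gaps
reported on real obstetric cohorts plausibly come from heterogeneous,
mixed-type clinical data that this generator deliberately does not
imitate. Both comparisons are therefore reported by `run_pipeline()`
(`baseline_report` for the raw-data SVM, `svm_pipeline_report` for the
identically-preprocessed one).

Equally, the published clinical figures (recall 0.768, F-score 0.728,
AUC 0.832 on the hospital cohort; biomarker-ratio AUCs up to 0.996) are
properties of undeposited patient data and are not reproduction targets
for this package; nothing in the test suite asserts them.

## Other numerical choices

- Min-max normalization maps constant features to 0 with a warning;
  fitted ranges are reusable on held-out data, with out-of-range values
  clipped to [0, 1].
- Missing-data policy on file input: feature columns with more than 20%
  missing entries are dropped, then remaining incomplete rows are
  dropped, both reported.
- ROC/AUC uses trapezoidal integration with tied scores collapsed into
  single threshold steps, making the area exactly the Mann–Whitney
  pair-counting probability with half credit for ties (verified against
  an independent pair-counting oracle and against `pROC`).
- The decision threshold for threshold-bound metrics defaults to 0.5 on
  the meta-learner probability; both classes' recalls are reported
  since either convention appears in the literature.
- All randomness flows through explicit seeds; stage seeds are derived
  deterministically from one master seed, and fixed-seed runs are
  byte-identical.
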