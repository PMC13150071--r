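---
title: "Attention-guided multiomics biomarker selection: models and methods"
author: "attnomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-guided multiomics biomarker selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`attnomics` implements a hybrid feature-selection pipeline for two-group
case-control multiomics studies — the motivating application is rheumatoid
arthritis with versus without anemia (labels `RA` / `RA_ane`) — together
with the clinical-epidemiology statistics that usually accompany such a
study. The selection funnel is:

1. modality-specific preprocessing (metabolite intensities; RNA-seq counts);
2. a classical differential layer (PLS-DA VIP + Student's t for
   metabolites; negative-binomial Wald tests for counts);
3. a leakage-confined scaler → PCA → transformer-encoder classifier whose
   attention weights yield a per-feature importance, evaluated by
   stratified 5-fold cross-validation;
4. a *dual filter*: the intersection of the classically differential
   features with the attention top fraction (default top 20%);
5. a five-model *algorithmic consensus* (KNN, RBF SVM, random forest,
   RFE-RF, gradient-boosted trees): features in every model's top-10;
6. a small diagnostic panel (default 5 features) fit as L2 logistic
   regression at a stratified 7:3 split and evaluated with a full metric
   array (ROC AUC, accuracy/precision/recall/F1, average precision,
   5-quantile-bin calibration, bootstrap AUC-difference intervals).

Every stage is exercised end to end on seeded synthetic data with planted
ground truth, so the package's guarantees are stated as testable
properties (null calibration, planted-feature recovery, leakage nulls,
reproducibility) rather than as re-derivations of any particular cohort.

# Preprocessing

**Metabolome.** Features with strictly more than 20% missing values are
removed; remaining missing entries are imputed with the per-feature
observed minimum (interpreting missingness as censoring at the detection
floor; a global minimum would couple unrelated assays); each sample is
sum-normalized and multiplied by a fixed constant of 10^4 before log10
transformation. The constant only shifts all log values uniformly; any
positive constant gives identical downstream statistics. Both thresholds
are strict inequalities. An optional QC relative-standard-deviation filter
exists but is disabled by default because the synthetic data model has no
QC injections.

**Transcriptome.** Genes with strictly more than 50% zero counts are
removed; library sizes are normalized with the median-of-ratios estimator
(the size factor of a sample is the median over all-nonzero genes of the
sample count divided by the gene's geometric mean). The attention and
panel stages consume `log2(count / size_factor + 1)`.

# Classical differential layer

**Metabolites.** VIP scores come from a NIPALS partial-least-squares
discriminant model after orthogonal-signal correction: `n_components - 1`
Y-orthogonal components (default one) are removed before a single
predictive component is fit, and
`VIP_j = sqrt(p * w_j^2)` for the normalized predictive weight vector, so
`mean(VIP^2) = 1` identically — a property asserted on every tested input.
Selection is `VIP > 1` and Student's-t `P < 0.05` (both strict, nominal,
deliberately without FDR: the composite threshold plus the downstream
attention intersection controls false positives instead; this mirrors the
practice of avoiding strict FDR in strongly collinear metabolite panels).
t-tests are pooled-variance, two-sided, on the log10 scale.

**Counts.** Per-gene dispersion is estimated by method of moments on
normalized counts (pooled within-group variance; floored at 1e-8), then
each group mean is fit by Newton iteration for the NB log-link MLE with
size-factor offsets — algebraically identical to the two-group NB GLM
because the design is orthogonal. The Wald statistic for the group
log-fold-change is referred to the standard normal; a development-time
null calibration (10 replicates × 2000 genes, n = 30/group) measured a
rejection rate of 0.051 at α = 0.05 for the normal reference versus 0.047
for a t reference, so the normal — also the field convention — is used.
Significance is `FDR < 0.01` (Benjamini–Hochberg) and symmetric
`|FC| > 2`, with fold change computed from mean normalized counts so that
equal group means give exactly `log2FC = 0`. Non-convergent fits fall back
to a flagged quasi-Poisson approximation. No empirical-Bayes dispersion
shrinkage is applied; the stage is intentionally self-contained, and the
test suite cross-checks direction and ranking against an independent
reference implementation on a fixture.

A proteomics-style filter (`|FC| >= 1.2`, inclusive, with nominal
`P < 0.05`) is provided for linear-scale abundance tables.

# The PCA–transformer and its attention importance

**Confinement.** Within every cross-validation fold, column
standardization and PCA (10 components for metabolome, 30 for
transcriptome) are fit on the training portion only and applied to the
held-out fold. The early-stopping validation split (a stratified 20% of
the fold's training portion) and the encoder's input scaling are likewise
computed on training data only. The acceptance suite verifies the
confinement operationally: across 10 label permutations at n = 200,
p = 500, the mean CV AUC stays in [0.45, 0.55], while a deliberate-leakage
mode is strictly higher.

**Deliberate-leakage mode.** Scaling/PCA fit on all data is not by itself
a label leak (both are unsupervised), so the probe mode additionally uses
the held-out evaluation fold as the early-stopping validation set — a
label-dependent leak through model selection that measurably inflates the
permuted-label AUC. The mode exists only as a regression probe.

**Architecture.** Each sample's component vector becomes `C + 1` tokens: a
learned classification token followed by one token per component, each
scalar score embedded to `embed_dim = 24` through a shared linear map plus
a learned positional embedding. Three pre-normalization encoder layers
(multi-head self-attention, then a ReLU feed-forward block of width 48,
each with residual connections and dropout 0.5 on the sublayer outputs)
are followed by a final LayerNorm; the sigmoid read-out sees only the
classification token. Heads: 2 (metabolome) / 6 (transcriptome). Training
minimizes binary cross-entropy with Adam (learning rates 5e-4 / 1e-4), L2
weight decay λ = 0.1 on weight matrices, batch size 4, at most 200 epochs,
early stopping at patience 8 / 10 epochs on the validation loss with the
best weights restored. All randomness (fold assignment, initialization,
batch order, dropout) flows from the configuration seed, so identical
configurations reproduce identical models bit for bit.

Three architectural choices deserve justification because they were made
after measuring alternatives on planted synthetic data:

* *Classification-token read-out (not mean pooling).* With mean pooling,
  label information reaches the classifier through the residual stream
  without passing through attention, and attention stays near-uniform —
  planted-feature recovery through the attention ranking was
  indistinguishable from a uniform baseline. Reading out only the
  classification token makes attention the sole route for evidence, which
  is what licenses interpreting its weights as importance.
* *Shared input scale.* Component scores are centred per component but
  scaled by the leading component's training-set SD. Per-component
  standardization erases the variance hierarchy — precisely the cue that
  distinguishes high-variance, potentially informative components — while
  raw scores destabilize the optimizer.
* *Pre-normalization.* Post-norm layers failed to converge within the
  patience window at these batch sizes without a warmup schedule;
  pre-norm layers train stably from the first epoch.

**From attention to features.** For each layer and head, the attention the
classification token pays to the component tokens is averaged over
samples, giving one distribution over components per (layer, head). These
distributions are combined by *negentropy weights*
(`log C - entropy`): a head that attends uniformly carries no
feature-selective information and receives ~zero weight, while a selective
head dominates. Measured on planted transcriptome data, a single
first-layer head attends 0.27 to the signal component while the remaining
17 (layer, head) pairs stay uniform; a flat average dilutes this signal
below the loading noise floor and planted genes then rank *last*, because
their loading mass concentrates on the one signal component while noise
genes accumulate absolute loadings across the whole bulk. If every head is
uniform the weighting degrades gracefully to the uniform distribution.
Per-feature importance is the absolute-loading-weighted sum
`imp_f = Σ_c |L_fc| · imp_c` (invariant to component sign flips), averaged
over folds; the top `ceil(0.2 p)` features (ties broken lexicographically
by feature id for reproducibility) form the attention set, taken over the
full preprocessed feature universe rather than the differential subset.

# Consensus and diagnostic panel

The dual-filter candidates are standardized and ranked by five models:
random forest (500 trees, impurity importance), gradient-boosted trees
(200 rounds, depth 3, learning rate 0.1, gain importance), RFE-RF
(iterative elimination of the worst half by forest importance; rank =
reverse elimination order), and KNN (k = 5) and RBF SVM through seeded
permutation importance (20 repeats, AUC drop when one column is permuted
at prediction time — neither model has a native importance). The consensus
is the intersection of the five top-10 lists, ordered by mean rank; it is
monotone in k and invariant to list order.

The diagnostic panel (first 5 features of the consensus, topped up by mean
rank when the intersection is smaller) is fit as ridge-penalized logistic
regression (fixed λ = 0.05; the penalty keeps coefficients finite under
perfect separation) on a stratified 7:3 split, with standardization fit on
the training partition only. Evaluation reports the full metric array on
both partitions; train ≥ test is reported, never asserted. The bootstrap
AUC-difference interval (percentile, 2000 stratified resamples) provides
the train-versus-test comparison.

# Clinical epidemiology layer

Anemia is flagged at hemoglobin < 120 g/l for males and < 110 g/l for
females (strict). Annual incidence per cohort is cases/tested with Wilson
score 95% intervals; exactly two cohorts per year are compared by
Pearson's chi-square without continuity correction (a Yates flag exists).
The hemoglobin–inflammation association fits three families on the same
design — OLS (Wald p, Bonferroni over the four tested markers only), ridge
regression (penalty by 5-fold CV over a fixed log-spaced grid), and a
random forest (impurity importance normalized to sum to one) — with age,
sex, disease duration and treatment class as adjustment covariates and
markers standardized, so linear coefficients are per marker SD. Post hoc
power uses the exact noncentral-t evaluation of the two-sided two-sample
t-test; it includes the opposite-tail rejection region, so it can differ
from `power.t.test` in the fourth decimal.

Over-representation of a selected feature set against GMT-style
annotation sets uses the one-sided hypergeometric tail `P(X ≥ k)` with
BH-FDR across sets; the universe is the features surviving preprocessing,
not the full annotation universe. Pathway topology ("impact") scores are
out of scope.

# The synthetic-data generators

The generators define the study conditions under which every guarantee is
tested; their defaults are fixed and not tuned per test.

* **Transcriptome:** gene means log-normal (`meanlog = log 80`,
  `sdlog = 1.4`); counts negative-binomial with the decreasing
  mean–dispersion trend `phi(mu) = dispersion_scale/mu + 0.01`
  (`dispersion_scale = 2`); per-sample library-size factors log-normal
  with CV 0.2; 5% of genes drawn at very low abundance so they exceed 50%
  zeros; planted genes multiply the second group's mean by
  `2^effect_log2fc`.
* **Metabolome:** feature-wise log-normal intensities on the raw scale
  (`meanlog ~ N(log 1e5, 1)`, `sdlog ~ U(0.25, 0.6)`) so that sum
  normalization and the log transform are genuinely exercised; MCAR
  missingness at 5% plus 5% of non-planted features forced above the 20%
  threshold; planted features shift the second group's log-mean by
  `effect_shift_sd` feature SDs.
* **Clinical:** four inflammatory markers correlated through a latent
  inflammation factor; hemoglobin is linear in the standardized markers
  with unit-scale noise, so planted coefficients are directly the
  recoverable standardized effects. ESR is left as a linear (unclipped)
  transform of its latent score so the planted effect is exactly linear.
* **Incidence:** per-year Bernoulli anemia outcomes at cohort-specific
  rates, realized as hemoglobin values consistent with the sex-specific
  thresholds, so the incidence estimator consumes raw records.

What the generators deliberately do **not** emulate: batch effects,
intensity-dependent (non-MCAR) missingness, correlated feature blocks
beyond the planted signal, multi-modal subpopulations, QC drift.
Passing tests therefore demonstrate the pipeline's statistical mechanics
— calibration, recovery, confinement, reproducibility — not robustness to
those real-data pathologies.

# Problem sizes and numerical choices

The validation suite runs the leakage null at n = 200 samples × 500
features (10 permutations), recovery at n = 80 × 500 (5 seeds), DE
calibration at 20 × 2000 null genes plus one planted run, and the full
pipeline at the reference size of 200 samples with 1000 metabolites / 2000
genes — sizes chosen as representative of a mid-scale clinical cohort
while keeping a complete validation run on a single CPU comfortably under
half an hour. The DE calibration band is three binomial SDs at the
single-replicate size (2000 genes): genes within a replicate share
estimated size factors, so the pooled 40000-test binomial SD would
understate the true sampling variance.

Other numerical conventions: ties in ROC AUC count 1/2 (midranks);
calibration uses quantile bins with ties kept together (constant
predictions collapse to one bin); zero-denominator classification metrics
return 0 with a degenerate flag; Wilson bounds are exact 0 and 1 at k = 0
and k = n; constant features are dropped from VIP with a warning; the
encoder aborts with a diagnostic on non-finite loss. The compiled training
kernel is asserted (to 1e-10) against a plain-R reference implementation
whose gradients are in turn checked against finite differences.

# Known limitations

* Attention-derived importance is a heuristic reading of a trained model;
  it is validated here against planted ground truth, not against causal
  feature relevance in real cohorts.
* The NB Wald test has no dispersion shrinkage, so very small cohorts
  (n ≲ 10/group) will be less stable than empirical-Bayes pipelines.
* Metabolite and transcriptome panels are never combined into one joint
  model; the pipeline treats the modalities as separate subcohorts.
* The consensus models use fixed, unoptimized hyperparameters; the stage
  is a stability filter, not a benchmark of tuned learners.
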