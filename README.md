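# attnomics

Attention-guided multiomics biomarker selection with clinical anemia
statistics.

`attnomics` is an R implementation of a hybrid feature-selection pipeline
for two-group case-control omics studies, built around the question of
which plasma metabolites and blood transcripts separate rheumatoid
arthritis patients with anemia (`RA_ane`, hemoglobin < 120 g/l in males,
< 110 g/l in females) from those without. It is aimed at biostatisticians
and computational biologists who want the whole funnel — preprocessing,
classical differential statistics, a leakage-confined deep-learning
importance layer, multi-model consensus, and diagnostic-panel evaluation —
as tested, seeded, composable functions rather than a one-off analysis
script.

## The method

Candidate biomarkers must pass **two independent filters**:

1. **Classical differential layer.**
   Metabolites: PLS-DA variable importance in projection after orthogonal
   signal correction, selecting `VIP > 1.0` and Student's-t `P < 0.05`
   (nominal, by design — the second filter replaces strict FDR control).
   Genes: per-gene negative-binomial Wald tests on median-of-ratios
   normalized counts, selecting `FDR < 0.01` and `|FC| > 2`.

2. **Attention layer.**
   Within each of 5 stratified cross-validation folds, standardization and
   PCA (10 components for metabolomics, 30 for transcriptomics) are fit on
   the training portion only, and a 3-layer multi-head self-attention
   transformer encoder (2 or 6 heads, dropout 0.5, weight decay
   λ = 0.1, Adam with modality-specific learning rates, early stopping) is
   trained on the component scores. The attention that the model's
   classification token pays to each component token, combined across
   heads and layers by negentropy weights and propagated through absolute
   PCA loadings, gives a per-feature importance
   `imp_f = Σ_c |L_fc| · imp_c`; the top 20% form the attention set.

The **dual filter** is the intersection of the two sets. It then feeds a
five-model **algorithmic consensus** (KNN, SVM, random forest, RFE-RF,
gradient-boosted trees; features in every top-10), and a 5-feature
diagnostic panel evaluated at a stratified 7:3 split with ROC AUC, average
precision, quantile-bin calibration, and bootstrap AUC-difference
intervals. A clinical layer provides annual anemia incidence with Wilson
score intervals and per-year chi-square cohort comparison, a multivariate
hemoglobin–inflammation association validated across OLS, ridge and
random-forest fits with Bonferroni correction, and exact noncentral-t
post hoc power.

Because cohort data of this kind are rarely public, the package ships
seeded synthetic-data generators with planted ground truth
(`generate_metabolome()`, `generate_transcriptome()`,
`generate_clinical()`, `generate_incidence()`); every guarantee the
pipeline makes — null calibration, planted-feature recovery, leakage
confinement, bit-level reproducibility — is phrased as a property of those
generators and enforced by the test suite.

## Worked example

A compact metabolomics run (about a minute on one CPU):

```r
library(attnomics)

params <- synth_omics_params(n_per_group = 40, n_features = 300,
                             n_planted = 15, effect_shift_sd = 2, seed = 11)
study <- generate_metabolome(params)
m <- sum_normalize_log10(impute_min(filter_metabolite_missingness(study$matrix)))
m
#> <omics_matrix> metabolome: 80 samples x 285 features
#>   groups: RA=40, RA_ane=40

y   <- study$truth$group_assignment
tt  <- student_ttest(m, y)
vip <- plsda_vip(m, y)
differential <- select_differential_metabolites(
  data.frame(tt, vip = vip[tt$feature_id]))

report <- cross_validate(m, y, attention_config("metabolome", seed = 12))
report
#> <attention_report> 5-fold CV, mean AUC 0.978; 57 features selected (top fraction)

panel <- dual_filter(differential, report$selected, universe = feature_ids(m))
length(differential); length(report$selected); length(panel)
#> 82   57   45

planted <- intersect(study$truth$planted_feature_ids, feature_ids(m))
length(intersect(panel, planted))
#> 14      # of 15 planted metabolites survive the dual filter
```

Fifteen of the 300 metabolites carry a planted 2-SD group shift. The
t/VIP layer flags 82 candidates, the attention layer independently ranks
57 features into its top 20%, and their intersection (45 features)
retains 14 of the 15 planted metabolites while discarding most of the
false positives — the dual filter trades a little recall for a much
cleaner candidate list. `consensus_panel()`, `fit_panel()` and
`evaluate_panel()` continue the funnel, and `run_pipeline()` executes the
whole flow for both modalities with one seed, writing every intermediate
plus a JSON manifest of the feature funnel.

The clinical helpers are direct calls:

```r
wilson_ci(5, 10)
#>   low  high
#> 0.237 0.763
two_sample_power(64, 64, d = 0.5)
#> 0.8015
```

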