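# transdx

Data-driven symptom subtyping for combined ASD/ADHD cohorts, with the
full validation chain: gap-statistic model selection over Ward
hierarchical clustering of symptom z-scores, subsample/adjusted-Rand
stability, linear discriminant validation, ANOVA/ANCOVA group comparisons
with partial η², Pearson correlation grids, and parallel mediation path
models with bias-corrected bootstrap intervals and ML fit indices
(RMSEA, CFI).

## Why

Children with autism spectrum disorder (ASD) and attention-deficit/
hyperactivity disorder (ADHD) rarely fit cleanly inside one diagnostic
box. An alternative is to cluster children directly on eight symptom
subscale z-scores (AQ: socialness, mindreading, patterns, details,
perseveration; SNAP-IV: inattention, hyperactivity/impulsivity, ODD) and
validate the resulting clusters externally against cognition (fine motor,
verbal fluency, executive function) and white-matter tract-mean
fractional anisotropy (FA). The package implements that pipeline for
biostatisticians who want each stage reusable and testable:

* `zscore()` / `invert_sign()` — standardized feature matrix
* `hierarchical_cluster()`, `gap_statistic()`, `internal_indices()` —
  clustering, `Gap(k) = mean_b log W*_kb − log W_k` with the
  one-standard-error selection rule, silhouette / Calinski-Harabasz /
  Dunn indices
* `subsample_stability()`, `adjusted_rand()` — recluster 80% subsamples,
  assign holdouts by LDA, score the combined labelling with the
  Hubert-Arabie ARI
* `fit_lda()` / `predict_lda()` / `confusion_and_accuracy()` /
  `pca_project()` — discriminant validation and visualization
* `anova_oneway()` / `ancova_oneway()` / `anova_from_summary()` /
  `bonferroni_posthoc()` / `chi_square_contingency()` — group statistics,
  including the summary-statistics bridge SS_B = Σ n_g(m_g − m̄)²,
  SS_W = Σ (n_g − 1)s_g² that recomputes published F values from printed
  "mean (SD)" cells
* `pearson_matrix()` / `heatmap_export()` — correlation structure
* `fit_path_model()` / `bootstrap_ci()` / `sem_ml_fit()` /
  `fit_indices()` — mediation a·b effects with BC bootstrap CIs and ML
  covariance fits
* `cohort_spec_groups()` / `cohort_spec_clusters()` /
  `generate_cohort()` / `generate_mediation_data()` — synthetic cohorts
  with the published group/cluster summary structure (the study data were
  never deposited)
* `run_pipeline()` — all of the above in order, from one `run_config()`

The numbered scripts under `analysis/` run the whole workflow as a
narrative and write tables/figures under `results/analysis/`.

## Worked example

```r
library(transdx)

cohort <- generate_cohort(cohort_spec_clusters(seed = 42))
config <- run_config(seed = 42, n_stability_reps = 200,
                     n_subjects = nrow(cohort))
report <- run_pipeline(config, cohort)
report
```

```
Transdiagnostic subtyping report
  subjects: 164
  selected k (gap): 3 | clustered at k = 3
  internal indices: silhouette 0.188, CH 41.75, Dunn 0.193
  stability ARI: mean 0.634 (min 0.436, max 0.926) over 200 reps
  LDA accuracy: resubstitution 93.3%, 5-fold CV 91.5%
  cluster x diagnosis chi-square: 19.42 (df 4, p 0.000651)
  mediation: a 0.117, b -0.145, c' -0.202, total -0.219 (n 99)
```

Reading it: the gap statistic detects three overlapping symptom clusters
(modest silhouette — real symptom clusters are not islands); the
partition is moderately stable under 80% subsampling (mean ARI 0.63); the
eight subscales separate the clusters well for a linear classifier
(93.3% resubstitution, 91.5% cross-validated); clusters cut across DSM
labels yet associate with them (χ² = 19.4, df 4); and across clusters 1
and 3 (n = 99 here), corpus-callosum FA, fine-motor skill and
perseveration show the expected signs in the mediation decomposition,
with the exact identity total = c' + a·b.

Published summary tables can be checked without raw data:

```r
t1 <- published_group_summaries()
anova_from_summary(t1[t1$variable == "socialness", ])$F
#> [1] 24.16979   # printed: 24.17
```

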