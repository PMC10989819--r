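# micromark

Discovery of disease-associated microbial markers from case/control
relative-abundance profiles, for microbiome researchers who suspect that
univariate differential-abundance tests are missing part of the story.

Statistical tests such as Kruskal–Wallis treat taxa independently and can
only flag features whose marginal case/control distributions shift. Many
disease-relevant taxa do not shift marginally — their signal lives in
interactions and nonlinear combinations. `micromark` selects markers
discriminatively instead:

1. **Rank** all features by random-forest *mean decrease accuracy*
   (out-of-bag permutation importance, averaged over replicate forests).
2. **Sweep** the ranked prefixes: for each top-*k* set
   (*k* = 5, 10, …, 60 by default), estimate the cross-validated AUC of a
   lightweight dense neural network (hidden layers 16 and 8, ReLU, L2
   penalty, Adam, cross-entropy loss). The *k* with the peak mean AUC
   defines the **marker set**.
3. **Characterize** the markers:
   * a directed interaction network from per-target regression-forest
     importances, refined by multiplying each adjacency row by the
     population variance of its off-diagonal entries
     (`M̂[i,·] = M[i,·] · σ²ᵢ`, amplifying hub rows), keeping the top 100
     links;
   * neural-network regression of clinical covariates (fasting blood
     glucose, BMI, age, weight) on marker abundances, ranked by Pearson
     r / p of out-of-fold predictions;
   * marker abundance patterns across covariate quantile bins (Q1–Q4),
     min-max normalized per marker, with per-feature Kruskal–Wallis
     significance classes.

A synthetic cohort generator with planted ground truth (shifted markers,
marginally *flat* interaction-coded marker pairs, planted directed
dependencies, covariates coupled to markers) lets every stage run and be
tested without external data.

## Worked example

```r
library(micromark)

cohort <- generate_cohort(cohort_config(n_case = 60, n_control = 60,
                                        n_features = 80, n_markers = 10,
                                        effect_size = 1.2, seed = 42))
fit <- micromark_fit(cohort$profile, cohort$metadata,
                     k_grid = seq(5, 30, by = 5),
                     families = c("nn", "random_forest", "knn"),
                     n_edges = 50, seed = 42)
fit
#> <micromark_fit>
#>   samples: 120, features ranked: 80
#>   selected markers: 10 (peak mean CV AUC 0.906)
#>   NN marker-set CV AUC: 0.907 +/- 0.091
#>   network: 50 edges kept
#>   leading covariate: fbg (r = 0.525, p = 7.17e-10)

mean(cohort$truth$marker_ids %in% fit$markers)
#> [1] 1
```

Reading the output: the AUC-versus-k curve peaked at k = 10, so the top 10
ranked features became the marker set — here all 10 planted markers
(recovery fraction 1). The neural network separates case from control with
mean cross-validated AUC 0.907 on those markers. Among the clinical
covariates, fasting blood glucose is the leading factor (largest
out-of-fold Pearson correlation, smallest p), matching how the generator
couples it to the markers with the least noise. `plot(fit)` draws the
AUC-vs-k curve, `summary(fit)` adds the classifier comparison and the
covariate ranking, `fit$edges` and `fit$hubs` hold the directed network,
and `predict(fit, new_profile)` scores new samples.

Real data enter through TSV tables:

```r
profile  <- read_abundance_table("species.tsv", orientation = "features_as_rows")
metadata <- read_sample_metadata("metadata.tsv")  # sample_id, label, fbg, bmi, age, weight
fit <- micromark_fit(profile, metadata, seed = 1)
```

Batch runs are driven by a YAML config via `run_pipeline()` (or the thin
CLI at `inst/cli/micromark.R`), which writes `markers.json`,
`cv_metrics.json`, `network_edges.tsv`, `network.graphml`,
`regression.json`, `stratified.tsv` and a `manifest.json` with parameter
echo and output hashes.

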