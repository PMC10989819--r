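---
title: "Methods: neural-network and random-forest marker discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neural-network and random-forest marker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Case/control metagenomic studies commonly select disease-associated taxa by
univariate differential-abundance tests. Such tests assume feature
independence and miss features whose marginal case/control distributions are
nearly identical but which carry predictive signal jointly — through
interactions with other taxa or through nonlinear structure. `micromark`
implements a discriminative alternative: features are ranked by how much a
random-forest classifier relies on them, and the marker set is defined as
the ranked prefix at which a small neural network's cross-validated AUC
peaks. Downstream stages characterize the selected markers: a directed
interaction network, neural-network regression of clinical covariates, and
quantile-stratified abundance patterns.

## The classifier at the core

The neural network is deliberately lightweight, sized for cohorts of a few
hundred samples: two dense hidden layers of 16 and 8 rectified-linear
units feeding one output node — logistic with cross-entropy loss for
classification, linear with mean-square-error loss for covariate
regression. Weights carry an L2 penalty; optimization is Adam on shuffled
mini-batches. The trainer is implemented directly in R matrix arithmetic:
at these problem sizes (tens of features, hundreds of samples) a 2,000-step
run takes well under a second, and a self-contained trainer keeps every
arithmetic step reproducible from a single integer seed.

Defaults (all overridable through `nn_spec()`): epochs 200, batch size 16,
learning rate 1e-3, L2 1e-4, He initialization. Early stopping is off; at
these sizes the fixed budget is cheap and keeps runs comparable. Four
comparison families run behind the same contract (`classifier_spec()`):
linear and RBF SVM (`e1071`, cost 1; RBF width `1/(p * var(X))`), a
500-tree probability forest (`ranger`), and 5-nearest-neighbours
(`class`). Scores are always oriented so that higher means more case-like.

Cross-validation is stratified by label — the spec of fold sizes is then
deterministic (e.g. 368 samples split 74/74/74/73/73) and minority-class
counts are stable. Feature standardization statistics are computed on the
training folds only and applied to the held-out fold; hard-label metrics
use a threshold of 0.5 on probability scores (0 on SVM margins), and AUC is
threshold-free. We report the standard AUC on `[0, 1]` — a classifier worse
than chance can score below 0.5.

## Marker selection

`rank_features()` scores every feature by mean decrease accuracy:
out-of-bag permutation importance of a random-forest classifier, averaged
over `n_permutations` (default 10) independently seeded 500-tree forests.
Averaging over replicate forests smooths the permutation noise of any
single run; a constant feature gets importance exactly zero, and ties are
broken lexicographically so the ranking is a reproducible permutation of
the feature set.

`topk_sweep()` then evaluates the neural network on the top-k prefix for
each k in a grid (species-scale default `5, 10, ..., 60`; a gene-scale
profile would use `5, ..., 100`). One fold assignment is shared across the
whole grid so the curve varies only with k. The marker set is the prefix at
the k with the highest mean AUC, smallest k on ties. The sweep is not
nested in an outer CV: the peak AUC is therefore an optimistically biased
estimate of generalization (the same folds chose k). Two unbiased
alternatives are provided: `evaluate_markers()` scores a fixed marker set
on an independent cohort (`make_holdout_split()` builds one by moving a
rounded-half-up fraction, default 30%, of controls next to external
cases), and `nested_sweep_evaluate()` repeats the whole
ranking-plus-sweep selection inside each outer training fold and scores
the fold-specific markers on the held-out fold — estimating how the
procedure, rather than one marker set, generalizes.

## Directed interaction network

`infer_adjacency()` follows the tree-ensemble network-inference recipe: for
each target feature, scaled to unit variance, a 1000-tree regression forest
predicts it from all other features with `sqrt(p-1)` candidates per split;
the directed weight i→j is feature i's variance-reduction importance for
target j, normalized so each target column sums to one.

The refinement step multiplies each row of the adjacency matrix
elementwise by the **population variance of that row's off-diagonal
entries**. A row whose outgoing weights are both strong and uneven — the
signature of a hub that dominates some targets — has elevated variance and
is amplified; a row with uniform weights is suppressed to zero. Design
choices worth stating: the diagonal (a structural zero) is excluded from
the variance so it cannot dilute it; the refinement is applied once, before
edge selection; and edges are ranked on the refined matrix. Because
"refinement" is sometimes used for the inverse convention, division by the
row variance is available behind `refine_adjacency(mode = "divide")`, but
multiplication — amplification of hub rows — is the default and the
documented behaviour. Scaling a row by c scales its refined row by c³, so
refined weights are comparable only within a run.

`top_edges()` keeps the 100 strongest directed links by default;
`hub_report()` counts distinct partners (a reciprocal pair is one
connection), with default thresholds of 5 and 10 partners.

## Covariate regression and stratification

`crossval_regress()` reuses the network with a linear output head and MSE
loss; the covariate is standardized on training folds and predictions are
returned in original units, each sample predicted exactly once out-of-fold.
Folds are balanced over the covariate's order so every fold spans its
range. Samples with a missing covariate are dropped listwise. Association
strength is the Pearson correlation between out-of-fold predictions and
observed values with the exact two-sided t-test p-value (n−2 df);
`rank_covariates()` orders covariates by ascending p (ties by |r|) and
calls the first the leading factor.

`stratify_profile()` bins a covariate at linear-interpolation quantiles
(quartiles by default), assigns samples to half-open intervals
`[b_{k-1}, b_k)` (last closed above) so assignment is total and
deterministic, averages each marker within each bin, and min-max
normalizes each marker row to `[0, 1]`; a constant row maps to zero with a
warning. Per-feature case/control significance uses the Kruskal–Wallis
rank test with tie correction at raw p < 0.05 — no multiple-testing
correction, matching the usual per-feature coloring of such heat maps;
apply `p.adjust()` to the returned p-values for a corrected view.

## The synthetic cohort generator

All tests run on cohorts from `generate_cohort()`, which emulates the
statistical structure the pipeline assumes, with planted ground truth:

* **Base abundances** are log-normal: per-feature latent means drawn from
  N(0, 1.5²), unit-variance per-sample noise on the latent log scale.
* **Shifted markers** get a latent mean shift of `effect_size` in cases,
  signs alternating so compositional closure stays roughly balanced.
* **Flat markers** come in pairs with identical marginals in both groups;
  the within-pair latent correlation is `+0.9` in cases and `−0.9` in
  controls. A rank test on either member stays at its nominal level, while
  the pair is jointly informative — the generator's encoding of markers
  that "matter without shifting".
* **Planted edges** add `coef * (source − mean)` to the target's latent
  value in topological order (the edge list must be a DAG).
* **Covariates** are weighted sums of coupled markers' latent values plus
  Gaussian noise, mapped to clinical units; fasting blood glucose is the
  least noisy and is shifted upward in cases, so it should rank first.
* **Structural zeros** at rate 0.3 per cell, then rows are closed to sum
  to one. We chose 0.3 as representative of species-level profiles
  restricted to moderately prevalent taxa; gene-level tables are sparser.

Two deliberate consequences. First, effects are planted on the latent log
scale, so realized compositional effect sizes are attenuated — closure and
zeros cost signal, and recovery thresholds in the tests allow for that.
Second, `structure_seed` (default: the sampling seed) fixes the
population — feature means, marker identities, signs, covariate weights —
separately from the sampling noise, so two configs sharing a
`structure_seed` are independent draws from the same population: that is
what a train/external-test pair means.

What the generator does **not** emulate: phylogenetic correlation among
features, abundance-dependent zero inflation, sequencing depth variation,
batch effects, or overdispersed count noise. Passing recovery tests on
these cohorts shows the machinery works under the assumed structure; it
does not promise the same numbers on real metagenomic profiles.

## Reference study conditions and problem sizes

The packaged checks run at desk scale, chosen to finish in minutes on one
CPU: cohorts of 100 cases / 100 controls with 200 features and 20 planted
markers (latent effect 1.0); the marker-recovery study uses 20 simulation
seeds, the flat-marker study 5, network recovery 5 (10-node DAG, 8 unit
edges, noise sd 0.25, n = 500), covariate recovery 10 (signal-to-noise
2:1). In the covariate-recovery check the covariate is coupled to the
markers' **realized** abundances: coupling through the latent scale first
would compound the stated 2:1 noise with the attenuation of closure and
structural zeros, and the check would then measure the generator's zero
rate rather than the regression machinery.

## Numerical and degenerate-input conventions

Undefined metrics (0/0, e.g. precision with no predicted positives) are
explicit `NA` values with a warning, excluded from fold aggregation with a
logged count — never silently zero. ROC ties move as one threshold block,
which makes the trapezoidal AUC equal the pairwise concordance
probability. Constant features: importance exactly 0; as a network target,
an all-zero column with a warning; in min-max normalization, a zero row
with a warning; in Kruskal–Wallis, H = 0 and p = 1. All-zero sample rows
are rejected in full profiles but tolerated after feature subsetting.
Quantile bins reject constant covariates. Every stochastic stage derives
its seed from one master seed through fixed per-stage offsets, so whole
pipeline runs are byte-reproducible.

## Known limitations

The sweep's peak AUC shares data with the choice of k (no nesting by
default). When the information in the markers saturates well before the
largest grid value, the AUC-vs-k curve is a noisy plateau and the argmax
drifts to larger k; the reported marker set is then conservative (a
superset) rather than wrong. Random-forest importance is a marginal-split
heuristic: purely interaction-coded features are ranked far above chance
but far below equally informative shifted features, so marker sets
recover flat markers only partially at these sample sizes. Network edge
weights are reliabilities, not effect sizes or tests; no significance is
attached. Regression r-values are in-cohort associations, not causal
claims.
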