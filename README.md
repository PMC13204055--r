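# mvpheno

Data-driven phenotyping of heterogeneous cohort data: multi-view Bayesian
factor analysis, demographic residualization, bootstrap consensus
clustering, effect-size phenotype profiling, and supervised
reconstructability validation.

## Who this is for

Epidemiologists and biostatisticians who have a cohort measured across
several thematic blocks of variables ("views": biochemistry,
anthropometry, questionnaires, ...) with missing entries, and who want
participant phenotypes that reflect coordinated multi-system variation
rather than chronological age or sex.

## What it computes

**Latent factors.** A probabilistic matrix factorization across views with
per-view likelihoods,

    x_nd | z, w ~ Normal(z_n' w_d, 1/tau_d)        (continuous views)
    x_nd | z, w ~ Bernoulli(sigmoid(z_n' w_d))     (binary views)

with N(0,1) priors on factor scores Z, automatic relevance determination
(ARD) priors on the loadings W (per-view, per-factor Gamma precisions),
and per-feature noise precisions. Inference is mean-field variational
Bayes (Jaakkola–Jordan bound for binary views); missing entries drop out
of every update — nothing is imputed. The ELBO is non-decreasing by
construction, which the tests verify iteration by iteration.

**Phenotypes.** Factor scores are residualized on age, age², and sex by
OLS; bootstrap consensus K-means (B resamples, k-means++ starts,
out-of-bag nearest-centroid assignment, Monti-style consensus ratios) is
run over a grid of K; K is selected by the sum of ranks over within-cluster
compactness, between-cluster separation, PAC, and bootstrap ARI; the final
partition comes from average-linkage aggregation of the consensus matrix.

**Validation.** Phenotype profiles (Kruskal–Wallis + BH-FDR, |mean Z| ≥
0.5 flags), centroid distances, one-vs-rest marker rankings (Cliff's δ,
SMD), demographic balance tests, and a reconstructability check: a
stratified 70/15/15 split (seed 42), 5-fold stratified CV of an xgboost
multiclass classifier, and a single held-out evaluation with per-class ROC
curves.

A synthetic multi-view cohort generator with known ground truth
(`generate_cohort()`) emulates the target data structure — 11 views, 118
features (97 Gaussian + 21 Bernoulli), ages 18–99, 74% female, planted
confounded factors and a planted 5-cluster structure — so the entire
pipeline is testable end to end.

## Worked example

```r
library(mvpheno)

cfg <- cohort_config(n_participants = 600, seed = 101)
report <- run_pipeline(cfg, k = c(8, 12), fit_seeds = 17,
                       k_grid_clusters = 4:7, B = 100)
print(report)
```

```
== Multi-view phenotyping report ==
Factor model: K = 12, EV_total = 0.523, converged
Inter-factor |r| max = 0.253 over 66 pairs
Confound audit: max |Spearman rho age| = 0.0129, max |Cohen's d sex| = 0.0000
Consensus: selected K = 5, sizes 142, 49, 191, 168, 50
ARI vs planted labels: 0.937
Reconstructability: CV macro-F1 0.843 +/- 0.116, CV AUC 0.982 +/- 0.017; holdout macro-F1 0.962, AUC 1.000
```

Reading this: the factor grid {8, 12} was fitted and K = 12 kept (maximum
total variance explained, here 52% of the observed-entry variance across
the 11 views — synthetic data are cleaner than real panels). After
residualization the factor scores carry essentially no age or sex signal
(|Spearman ρ| ≈ 0.01, Cohen's d ≈ 0). The consensus stage picked K = 5
from the 4–7 grid by sum of ranks; the recovered partition matches the
planted 5-cluster truth with ARI 0.94, and the two small recovered groups
mirror the two small planted clusters. The phenotype labels can be
reconstructed from the 118 original features with high fidelity — high
because the labels were derived from those same features; this is an
internal consistency check, not external validation.

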