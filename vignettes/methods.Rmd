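---
title: "Multi-view factor analysis and consensus phenotyping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view factor analysis and consensus phenotyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvpheno)
```

## The problem

Cohort studies of human aging collect heterogeneous data — biochemistry,
anthropometry, physical and cognitive function, sleep, lifestyle and social
questionnaires — on the same participants. **mvpheno** implements a
data-driven phenotyping pipeline for such data: it compresses the many
correlated variables into a small number of latent factors shared across
data views, removes demographic confounding from the factor scores, groups
participants into phenotypes by stability-selected consensus clustering,
characterizes the phenotypes by nonparametric effect sizes, and checks how
well the unsupervised labels can be reconstructed from the original
variables with a supervised classifier.

## The factor model

Each view $m$ is an $N \times D_m$ matrix $X^{(m)}$ with entry-level
missingness. The model is a probabilistic matrix factorization with
per-view likelihoods:

$$x^{(m)}_{nd} \mid z_n, w_d \sim
  \begin{cases}
  \mathcal N\!\left(z_n^\top w_d,\; \tau_d^{-1}\right) & \text{Gaussian views}\\[2pt]
  \mathrm{Bernoulli}\!\left(\sigma(z_n^\top w_d)\right) & \text{Bernoulli views}
  \end{cases}$$

with priors $z_{nk} \sim \mathcal N(0, 1)$,
$w_{dk} \sim \mathcal N(0, \alpha_{mk}^{-1})$, and Gamma hyperpriors on the
ARD precisions $\alpha_{mk}$ (per view and factor) and the noise precisions
$\tau_d$ (per Gaussian feature). The ARD precisions shrink factor–view
blocks that carry no signal toward zero, effectively pruning unused
factors; noise precisions are per-feature because mixed clinical panels are
heteroscedastic.

Inference is mean-field variational Bayes. Every update is exact coordinate
ascent on the evidence lower bound (ELBO), so the ELBO trace is
non-decreasing to floating-point precision — this is the core correctness
test of the implementation. Bernoulli likelihoods use the Jaakkola–Jordan
quadratic lower bound with one variational parameter $\xi_{nd}$ per
observed entry, updated in closed form each sweep. Missing entries simply
drop out of every sum; nothing is ever imputed.

Numerical choices:

* **Initialization.** Factor scores start from the PCA of the concatenated
  views (missing entries mean-filled *only* for this initialization), with
  a small seed-controlled Gaussian perturbation; loadings start from the
  corresponding least-squares regression. This stabilizes ELBO paths;
  reproducibility across seeds is then verified empirically with the
  Procrustes stability audit rather than assumed.
* **Convergence.** The fit stops when the relative ELBO change over a
  5-iteration window falls below `tol` (default `1e-4`), capped at
  `max_iter = 2500` iterations.
* **View scaling.** With `scale_views = TRUE` each Gaussian view is divided
  by the SD of its pooled observed entries after column z-scoring, so no
  view dominates the likelihood through sheer dimensionality or scale.
* **Identification.** Factors are returned ordered by decreasing variance
  explained, each sign-flipped so its largest-magnitude loading is
  positive. Reported factor scores are mean-centered across the sample
  (`factor_scores()`).
* **Hyperpriors.** All Gamma hyperpriors default to the broad
  $(10^{-3}, 10^{-3})$; they are exposed in the call.

### Variance explained

`variance_explained()` reports, per factor $k$ and view $m$,
$1 - \mathrm{SS}(X^{(m)} - z_k w_k^\top)/\mathrm{SS}(X^{(m)})$ over the
observed entries of the scaled view, and an overall `ev_total` from the
full-$K$ reconstruction, aggregated across views weighted by the number of
observed entries. Gaussian views enter on the linear scale with uncentered
total SS (they are standardized, so their column means are zero anyway);
Bernoulli views keep their 0/1 coding, are reconstructed on the
probability scale $\sigma(z^\top w)$, and their total SS is taken around
the observed feature means — the model has no per-feature intercept, so
single-factor cells for unbalanced binary features can be slightly
negative; per-cell values are clipped to $[-0.05, 1]$ for reporting.
`mvfa_select_k()` fits a grid of $K$ values over several seeds and returns
the fit with maximal `ev_total`, together with seed-median summaries and
the mean pairwise Procrustes stability per $K$.

Because factor models are rotation-identified only through the ARD
structure, run-to-run agreement is measured after orthogonal Procrustes
alignment of the stacked loading matrices
(`procrustes_stability()`), which is invariant to factor permutations and
sign flips. Near-orthogonality of the resulting factor scores is an
empirical property, not a constraint; `factor_correlation_audit()`
quantifies it over all $K(K-1)/2$ pairs.

## Residualization

Chronological age and sex structure many of the factors. For each factor,
`residualize_factors()` fits ordinary least squares on
$[1, \mathrm{age}_c, \mathrm{age}_c^2, \mathrm{sex}]$ and keeps the
residuals. Age is centered before squaring to curb collinearity between the
linear and quadratic terms; whether the original analysis did so is a
convention we fix and document here — the residuals themselves are
identical either way because the two designs span the same column space.
Residuals are exactly orthogonal to every design column (an algebraic OLS
property, tested at machine precision), and residualizing twice is a
no-op. Residuals are *not* re-standardized before clustering; the audit
(`confound_audit()`) reports per-factor Spearman correlation with age and
Cohen's d by sex, before and after.

## Consensus clustering

Phenotypes are derived from the residualized scores by bootstrap consensus
K-means (`consensus_cluster()`). For each candidate $K$ (default grid
4–9):

1. For $b = 1, \dots, B$ (default 300): resample $N$ participants with
   replacement, run K-means on the unique resampled rows (k-means++
   initialization, 10 restarts, seed `base_seed + b`), and assign *every*
   participant — in-bag or out-of-bag — to the nearest centroid, giving a
   full-length replicate partition. Out-of-bag assignment makes all
   downstream metrics well-defined on the whole cohort.
2. The consensus entry for a pair is the Monti-style ratio: co-clustering
   count divided by co-sampling count, counting only replicates in which
   both members were in-bag. Co-sampling counts are retained for audit.
3. The candidate partition at this $K$ is obtained by average-linkage
   hierarchical clustering of $1 - \text{consensus}$.
4. Four stability metrics are computed: within-cluster compactness and
   between-cluster separation (mean consensus over same- and
   different-cluster pairs), PAC (the fraction of consensus entries
   strictly between 0.1 and 0.9 — the standard thresholds, exposed in the
   call), and the mean bootstrap ARI of the replicate partitions against
   the consensus partition.

$K$ is selected by the sum of ranks over the four metrics (compactness
high, separation low, PAC low, ARI high; ties get average ranks and are
broken toward smaller $K$). The published definitions of "compactness" and
"separation" for this family of pipelines are not unique; the mean-consensus
reading used here is the simplest one consistent with their reported
magnitudes, and it is what the tests pin down.

## Phenotype characterization

`cluster_factor_profiles()` reports per-cluster mean residualized factor
scores, a tie-corrected Kruskal–Wallis test per factor with
Benjamini–Hochberg adjustment across the family of factors, and flags for
cluster–factor cells with $|\bar z| \ge 0.5$ SD. The demographic tests
(Kruskal–Wallis for age, chi-square for sex, with an exact-test fallback
when expected cells drop below 1) form their own BH family — the
literature this follows does not state whether the two families were
pooled; keeping them separate is the conservative reading for the factor
tests. Centroid distances are Euclidean norms of cluster means in the
residualized (hence cohort-centered) factor space. Markers are ranked
one-vs-rest by Cliff's $\delta$ (midrank implementation, exactly equal to
the $O(n^2)$ pairwise definition, ties counting as neither greater nor
less) alongside the standardized mean difference with pooled SD.

## Reconstructability

`split_cohort()` makes a stratified 70/15/15 train/validation/test split
with largest-remainder rounding (1201 participants yield exactly
841/180/180) and a fixed default seed of 42. `crossval_classifier()` runs
stratified 5-fold CV of a gradient-boosted tree classifier (xgboost
backend: 500 trees, depth 6, learning rate 0.1, no hyperparameter search;
any backend with the same `fit`/`predict_proba` contract can be plugged
in), reporting macro-F1 and one-vs-rest ROC-AUC as mean ± SD.
`evaluate_holdout()` refits on the training part with early stopping on
the validation part and evaluates once on the test part, producing
per-class ROC curves; the trapezoidal AUC equals the Mann–Whitney rank
statistic exactly, and both routes are implemented and cross-checked.

The labels are produced once, on the full cohort, before any splitting —
the factor model and clustering are never refit per fold. The metrics
therefore quantify *internal reconstructability* of the partition from the
feature space, not generalization to an independent cohort.

## The synthetic cohort generator

Because the motivating study's individual-level data are not publicly
depositable, validation rests on `generate_cohort()`, which emulates the
data's statistical structure with known ground truth: 1201 participants by
default, 11 views with 118 features (97 Gaussian-modeled continuous, 21
Bernoulli-modeled binary in a 15 + 6 split, per-view counts 5–40), ages
uniform on 18–99 with 74% female, and 8 latent factors. True scores are
cluster centroid + standard-normal within-cluster noise + confound terms
($\beta_{\text{age}}$ per year and $\beta_{\text{age}^2}$ per year$^2$
applied to age centered at the range midpoint, $\beta_{\text{sex}}$ on the
level coded 1); Gaussian views are $ZW^\top$ plus Gaussian noise (SD 1),
Bernoulli views are draws from $\sigma(ZW^\top)$; loadings are
$\mathcal N(0, 0.3^2)$ inside each view's active-factor mask and exactly
zero outside, emulating ARD-pruned structure; missingness is MCAR at 10%
per view (the study reports varying completeness but no rates; MCAR is the
simplest mechanism consistent with retaining the full cohort, and the rate
is a config field).

The five planted clusters sit at the vertices of a regular simplex in the
first five factor dimensions, pairwise 5.5 within-cluster SD apart,
centered at the proportion-weighted mean (proportions echo the study's
cluster shares). The simplex geometry is deliberate: the factor model's
unit-variance prior on $Z$ rescales each latent dimension by its total SD,
so cluster structure concentrated on a single axis with huge
between-cluster variance would be compressed relative to noise-only axes.
Spreading the structure across several dimensions keeps the planted
geometry recoverable after that compression, and 5.5 SD puts the mixture's
Bayes error near 0.1%, so a failure to recover the partition indicts the
pipeline, not the data. With these defaults the planted structure is
unambiguous at the scale used in the tests ($N = 600$: factor grid
\{8, 12\}, consensus grid 4–7 with $B = 100$ — sizes chosen so the whole
validation runs comfortably on one CPU); the generator's `ev_total` is
higher than is typical for observational cohort panels, which is the main
respect (besides realistic marginals, item response patterns, and
non-random missingness) in which passing tests do not certify behaviour on
real data.

## Worked example

```{r example, eval = FALSE}
cfg <- cohort_config(n_participants = 600, seed = 101)
report <- run_pipeline(cfg, k = c(8, 12), fit_seeds = 17,
                       k_grid_clusters = 4:7, B = 100)
print(report)
```

## Known limitations

* One Gaussian/Bernoulli likelihood pair; no count or ordinal likelihoods.
* ARD-only sparsity (no spike-and-slab), single participant group.
* Linear-plus-quadratic age adjustment only; no spline alternative.
* The consensus stage assumes Euclidean geometry of the residualized
  scores; alternative base clusterers are out of scope.
* The reconstructability check is an internal consistency measure by
  construction; external validity requires an independent cohort.
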