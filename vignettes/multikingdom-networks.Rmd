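---
title: "Multi-kingdom co-occurrence networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-kingdom co-occurrence networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

kingdomnet infers and analyses signed co-occurrence networks spanning
several biological kingdoms — plants, nematodes, fungi, bacteria, archaea —
from marker-gene count tables and a binary plant survey. This vignette is
the package's own account of the science behind each stage: the models, the
tunable parameters and the reasoning behind the defaults, what the
synthetic-data generator does and does not emulate, and the numerical
conventions a careful reader will want spelled out.

## The inference model

Marker-gene counts are *compositional*: each sample's counts are a
multinomial draw whose total (sequencing depth) carries no biological
information, so correlations between raw relative abundances are distorted
by closure. The package follows the sparse inverse-covariance approach
developed for microbial data: assume a latent log-abundance vector per
sample with a sparse precision (conditional-dependence) structure, undo the
closure with a centred log-ratio (CLR) transform, and estimate the
conditional-dependence graph rather than the correlation graph.

Because each kingdom is sequenced with its own marker and library, each
kingdom's counts form their *own* composition. `clr_transform()` therefore
applies the CLR per kingdom block — `log(x + pseudocount)` centred by the
sample's within-block mean log — and concatenates the blocks; the binary
plant block is sent through the same transform with 0/1 treated as counts
(a raw-binary route would also be defensible; the CLR route keeps all
blocks on one scale and is the cross-domain convention).

Edges are estimated by Meinshausen–Bühlmann neighbourhood selection: one
lasso regression of every taxon on all others
(`mb_neighborhood_selection()`). Two conventions matter:

* **Scale.** Regressions run on column-standardized data (the correlation
  scale), matching the reference implementations of this method family.
  The penalty path (default 20 log-spaced values) runs from the maximum
  absolute off-diagonal correlation — at which the graph is exactly
  empty — down to 1/100 of it.
* **Symmetrization.** Edge support uses the OR rule (an edge exists if
  either directed regression selects it); the AND rule suppresses exactly
  the weak cross-kingdom edges this analysis is about. The edge sign is
  the sign of the directed coefficient with the larger magnitude, the
  weight the mean of the two magnitudes.

The penalty is chosen by StARS (`stars_select()`): refit on random
80% subsamples (default 50), measure per-edge selection instability
`2 f (1 - f)` averaged over all pairs, and take the densest penalty whose
running-supremum instability stays at or below `beta = 0.05`. These are the
conventional StARS defaults; the instability average lies in [0, 0.5]
(the algebraic maximum of `2 f (1 - f)`), not [0, 0.25].

**Known limitation.** The CLR's within-block centring is a rank-one
distortion that shrinks as block size grows. With blocks of ten or fewer
taxa it is substantial: single-kingdom inference on very small blocks tends
to select nothing stable (StARS then warns and returns the sparsest
penalty) and exhibits a negative-correlation bias. Benchmarks in the test
suite therefore use blocks of 15–20 taxa.

## The synthetic world

`make_synthetic_dataset()` generates everything downstream stages consume,
with known ground truth:

* **Counts** come from a logistic-normal multinomial: latent Gaussian
  samples with a block-structured sparse precision matrix
  (`make_precision_matrix()`), softmax to compositions, multinomial draws
  at log-normal depths (median 5000, log-sd 0.3 — a typical MiSeq spread;
  the source study does not report per-kingdom depth distributions).
  The precision support *is* the truth edge set; off-diagonal magnitudes
  are 0.3 (the standard value in sparse-recovery benchmarks), the
  diagonal is boosted deterministically until the condition number is at
  most `condition_cap = 100`, and the recorded association sign is the
  *negative* of the precision entry's sign, because a partial correlation
  has the opposite sign of its precision coefficient. 35% of associations
  are negative by default, the share observed in the multi-kingdom
  timberline network.
* **Plant presences** are Bernoulli with a logistic link on the
  (standardised) latent abundance of linked taxa — conditioning on latent
  values, not counts, keeps the association strength independent of
  sequencing depth.
* **Environment** is one dominant sorted gradient (an elevation/pH
  stand-in) plus independent noise variables, with optional near-duplicate
  columns (|r| > 0.7) for exercising the collinearity filter.

What a green test on this world establishes: the estimator recovers sparse
conditional-dependence structure from compositional counts at realistic
sample sizes (F1 at least 0.7 at p = 50, n = 200), and every bookkeeping
and statistical operation downstream is exact. What it does not establish:
robustness to real-data features the generator omits — zero inflation
beyond the multinomial's, taxon-specific depth biases, guild structure in
the truth graph, spatial autocorrelation among samples.

## Preprocessing conventions

* Rarefaction subsamples each sample without replacement to the minimum
  depth. Each column's draw is keyed on the *sample id*, not the column
  position, so a fixed seed gives results invariant to column order.
* The prevalence filter keeps taxa with nonzero counts in at least 5
  samples (the source convention), applied after rarefaction — the filter
  belongs to network construction, so it sees the tables the network
  sees.
* The collinearity filter (threshold |r| > 0.7, Pearson, untransformed) is
  greedy: while any violating pair exists, the member of the
  worst-offending pair with the larger mean absolute correlation to the
  other retained variables is dropped, exact ties dropping the
  later column. Zero-variance variables are dropped first with a warning.

## Topology, roles, stability

`topology_summary()` reports node and edge counts, mean connectivity
(2E/N), modularity of a seeded Louvain partition (resolution 1) on the
unsigned unweighted graph, and the mean shortest-path length over reachable
pairs; an edgeless graph reports 0 for both modularity and path length
(the convention the published single-kingdom nematode row uses). Node roles
reuse the *same* seeded Louvain partition, so modularity and role
classification never disagree about modules.

Within-module degree z uses the sample standard deviation (n − 1
denominator; a zero-variance or singleton module yields z = 0), and the
participation coefficient is `1 - sum_s (k_is / k_i)^2`. Roles follow the
classical z–c thresholds (z = 2.5, c = 0.62) with the boundary convention
z ≥ 2.5 counting as hub and c > 0.62 as connector. A connector therefore
needs links into at least three modules (a two-module split caps c at 0.5).

Natural connectivity — `ln((1/N) sum_i exp(lambda_i))` over the unsigned
adjacency spectrum — is computed with a log-sum-exp guard, exact for
complete graphs up to the largest eigenvalues encountered.
`robustness_curve()` removes uniformly random nodes (the removal strategy
is unstated in the source; targeted attacks are out of scope) one at a time
to 50%, averages over replicates (default 100), and fits an OLS slope.

**Slope units.** Raw natural connectivity grows with network size and
density, so raw slopes only rank networks of similar scale; adding a
kingdom almost always steepens the raw slope even when decay becomes
proportionally slower. `robustness_curve(normalize = TRUE)` rescales the
curve by its unperturbed value, and `add_kingdom()` compares stability on
that proportional scale. The published slopes (≈ −0.018 per percent
removed, i.e. −1.8 per unit fraction) are consistent with a proportional
scale; since the original units are unstated, slope *orderings*, not
values, are the reproducible claim. The stabilizing effect of adding a
densely cross-linked kingdom is itself condition-dependent: it appears
when the base kingdom's own association structure is sparse and fragile
(as for the published plant and archaeal networks) and can reverse when
the base is already redundant.

## Cross-kingdom statistics

`decompose_links()` books each edge into one unordered kingdom pair.
Expected link proportions for a focal kingdom are the non-focal kingdoms'
node shares; preference deviates are observed minus expected, in the units
supplied. The null ensemble is G(n, m) — node and edge counts fixed
exactly, per the source's construction — with the observed multiset of
edge signs permuted onto the random edges, preserving the global
positive:negative ratio exactly. The ensemble does not preserve per-block
densities or degrees (a configuration-model null is deliberately out of
scope). Z-scores are `(observed − mean)/sd` over the ensemble; a
zero-variance ensemble flags Z as undefined rather than returning an
infinity.

## Community-level regression

Bray–Curtis (counts), Jaccard (presence/absence) and great-circle
(haversine, R = 6371 km) distances feed `mrm()`, which unfolds lower
triangles, fits OLS, and draws significance from joint row/column
permutations of the response matrix with the add-one correction — the
standard Mantel-type scheme. Distances are z-scored by default so
coefficients are comparable across predictors; `standardize = FALSE` gives
raw-scale coefficients (where exact linear dependence `response = 2 ×
predictor` returns coefficient 2). Two all-zero samples yield distance 0
with a warning; predictor pairs with |r| > 0.99 are rejected by name. The
nested pair of models (environment/space/plants, then plus other kingdoms'
community distances) inherits `R²(MRM2) ≥ R²(MRM1)` from OLS nesting.

## Reproducibility

Every stochastic operation takes an explicit seed; the pipeline
(`run_pipeline()`) threads per-stage seeds from its configuration and
writes a manifest with md5 checksums, so identical configuration implies
bit-identical artifacts. Louvain, StARS subsampling, rarefaction, null
ensembles and permutation tests all restore the caller's RNG state.
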