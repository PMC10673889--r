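---
title: "Optimal-transport factorization of paired multi-omics data: model and methods"
author: "otOmics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal-transport factorization of paired multi-omics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otOmics)
```

## The model

Paired multi-omics experiments measure $d$ molecular modalities (RNA,
chromatin accessibility, surface proteins, ...) in the *same* $n$ cells.
After preprocessing, each modality $p$ is a nonnegative matrix
$A^{(p)} \in \mathbb{R}_+^{m_p \times n}$ whose columns are normalized to
sum to 1, i.e. each cell is a discrete probability distribution
(histogram) over features.

otOmics decomposes all views jointly,
$A^{(p)} \approx H^{(p)} W$, into omic-specific **dictionaries**
$H^{(p)} \in \mathbb{R}_+^{m_p \times k}$ and one **shared embedding**
$W \in \mathbb{R}_+^{k \times n}$, with all columns constrained to the
probability simplex. Unlike Euclidean NMF, the reconstruction error is
measured by entropy-regularized optimal transport,
$$
\mathrm{OT}_\varepsilon(a, b) \;=\; \min_{P \in \Pi(a,b)}
\sum_{k,l} P_{k,l} C_{k,l} \;-\; \varepsilon E(P),
\qquad E(X) = -\sum_{i} X_i \log X_i ,
$$
where $\Pi(a,b)$ are the couplings with marginals $a$ and $b$ and
$C^{(p)}$ is a data-driven **ground cost**: the pairwise cosine distance
between feature profiles (rows of $A^{(p)}$). Transporting mass between
co-expressed features is cheap, so the loss exploits feature similarity
instead of treating features as orthogonal coordinates.

The objective is
$$
\sum_p \Big( \sum_{j=1}^n \mathrm{OT}_\varepsilon\big(H^{(p)} w_j,\,
a^{(p)}_j\big) \;-\; \rho_p E(H^{(p)}) \;-\; \mu E(W) \Big),
$$
where the entropy penalties (with value $-\infty$ off the simplex) both
enforce the simplex constraints and control sparsity: $\rho_p$ and $\mu$
are softmax coldness parameters, so $\mu \to 0$ assigns each cell to a
single factor and $\mu \to \infty$ spreads cells uniformly over factors.
Note the embedding entropy appears once per modality (inside the sum over
$p$); the joint dual below and its softmax recovery carry the matching
$d\mu$ coefficient, and `totalLoss()` uses the same convention so that
block updates are exactly monotone for the audited loss.

### Parameter scaling

To make the sparsity parameters comparable across omics and datasets they
are rescaled by the problem dimensions:
$$
\rho_p = \frac{\tilde\rho_p}{\log(m_p)\, k}, \qquad
\mu = \frac{\tilde\mu}{\log(k)\, n}.
$$
Defaults $\tilde\rho_{\mathrm{rna}} = \tilde\rho_{\mathrm{adt}} = 0.01$,
$\tilde\rho_{\mathrm{atac}} = 0.1$, $\tilde\mu = 0.001$. The latent
dimension defaults to $k = 5$ for three-population/controlled data and
$k = 50$ is the usual choice for heterogeneous atlases. $k = 1$ is
rejected ($\log k = 0$).

### Optimization

Each block subproblem (all $H^{(p)}$ with $W$ fixed; then $W$ with all
$H^{(p)}$ fixed) is solved through its smooth Fenchel dual in the
variables $G^{(p)} \in \mathbb{R}^{m_p \times n}$:
$$
\min_{G}\; \sum_j \mathrm{OT}^\star_\varepsilon(g_j, a_j)
 + \rho_p\, (-E)^\star\!\big(-G W^\top / \rho_p\big),
\qquad
H^{(p)} = \mathrm{softmax}\big(-G W^\top / \rho_p\big),
$$
and jointly over all modalities for the embedding with coefficient
$d\mu$ and
$W = \mathrm{softmax}\big(-\tfrac{1}{d\mu}\sum_p H^{(p)\top} G^{(p)}\big)$.
Here $\mathrm{OT}^\star_\varepsilon(g, a) = \varepsilon \sum_l a_l\,
\mathrm{LSE}_k\!\big((g_k - C_{k,l})/\varepsilon\big) + \varepsilon E(a)$
is the Legendre conjugate of the transport loss in its first argument
(its gradient is the source marginal of the optimal plan — a histogram),
and $(-E)^\star$ is a column-wise log-sum-exp. One sign in the printed
dual of the source derivation is reproduced here as derived from the
Fenchel conjugate (a `+` on the $(-E)^\star$ term under `min`); the
package verifies strong duality numerically — minus the dual optimum
equals the primal block minimum — in its test suite.

The duals are smooth but stiff: the $(-E)^\star$ term has coldness
$1/(d\mu) \sim 10^4$–$10^5$, which makes it near piecewise-linear.
L-BFGS (history 10) handles this, but the projected gradient rarely
reaches small norms; the effective inner stopping rule is the relative
objective-change criterion of L-BFGS-B (`innerFactr = 1e7`, i.e. about
`2e-9` relative) with a generous iteration cap (`innerMaxIter = 3000`)
and warm starts of the dual variables across outer iterations. Outer
alternation stops when the relative loss change falls below
`lossRTol = 1e-5` or after `outerMaxIter = 100` iterations, and aborts
with diagnostics if the loss increases relatively by more than $10^{-6}$
for three consecutive outer iterations.

The recorded loss trace reuses the embedding-step dual optimum (equal to
the primal reconstruction-plus-embedding-entropy value by strong
duality) plus the directly computed dictionary entropies; a full
Sinkhorn-based primal evaluation runs every `auditEvery = 10` iterations
and the largest relative discrepancy is stored in the fitted model
(`auditDrift`; around $10^{-4}$ or below on the reference runs).

Two numerical paths evaluate the transport kernels. When
$\max(C)/\varepsilon < 600$ the shifted kernel $e^{-C/\varepsilon}$ is
representable and log-sum-exp matrices reduce to BLAS matrix products;
otherwise a per-feature loop with full max-shift stabilization is used,
finite for $\varepsilon$ down to $10^{-3}$ on costs bounded by 2 (and
below). Zero-mass bins receive $-\infty$ log-potentials and zero plan
rows without NaN.

### Initialization and reproducibility

The dual warm start is a seeded feature-wise Gaussian
($\sigma = 0.1$, constant across cells) and the initial embedding is a
column-wise softmax of a seeded random projection of the first view.
Both choices are deliberately *cell-order equivariant*: permuting the
cells permutes the optimization problem exactly, so embeddings of
permuted datasets agree up to solver tolerance (about $10^{-4}$ at tight
inner settings; exact equivariance of the fitted numbers would require
exact block minima). With a fixed seed the fit is bit-reproducible.

### Why $\varepsilon = 0.05$

The source derivation never states $\varepsilon$. Cosine costs of
nonnegative data live in $[0, 1]$; $\varepsilon = 0.05$ is small enough
that the entropic loss tracks unregularized transport (the package
verifies a $10^{-2}$ agreement of the transport-cost part with exact
linear programming at $\varepsilon = 10^{-3}$ on small problems) yet
large enough for fast, stable Sinkhorn iterations. It is config-exposed
(`modelConfig(eps = ...)`) and logged by the pipeline.

## Preprocessing recipes

Per modality, `preprocessDataset()` applies the standard single-cell
recipes and ends with the simplex projection the model requires:

* **RNA**: QC filters (thresholds are configuration values with *no*
  defaults — they are disabled unless set), total-count normalization to
  10000, $\log(1+x)$, selection of the top 2500 variable genes, simplex
  projection.
* **ATAC**: either the same lognorm route or TF-IDF; top-peak selection
  (presets 1500/5000/15000 depending on dataset scale); simplex
  projection.
* **ADT**: centered log-ratio with pseudocount 1 (raw tag counts contain
  zeros), no QC or feature selection; simplex projection. CLR output is
  signed, so `toSimplex()` shifts each column by its minimum first and
  reports that it did.

Variable features are ranked by the classic mean-binned normalized
dispersion (variance/mean z-scored within 20 equal-count mean bins, ties
broken by feature index). The TF-IDF dialect is
$TF = x_{fc}/\sum_f x_{fc}$ and
$IDF = \log(1 + n/(1 + n_{\mathrm{open}}(f)))$, chosen because the name
alone does not pin a formula; the pseudocount keeps features open in no
cell finite. Both choices are deterministic and config-switchable.

## The synthetic controlled settings

`simulateMultiOmics()` generates three separable cell populations
(default $3 \times 50$ cells) in two coupled count views (default 100
features each): population-specific 25-feature programs with
Gamma-distributed means (mean 8 against a 0.6 background) and Poisson
counts, then a seeded mask that raises the overall zero fraction to 65%.
ATAC-like features carry `chrom:start-end` identifiers so the BED export
path is exercised. Four transformations reproduce the controlled
settings used to probe integration methods:

* `mixInRNA()` — population 1's RNA profiles are replaced by profiles of
  population-2 cells sampled uniformly *with replacement* (the sampling
  convention is a package decision; the source text does not specify
  it), leaving ATAC untouched: RNA alone cannot separate populations 1
  and 2 (the merged-pair ceiling for a 50/50/50 design is ARI = 0.568).
* `mixInBoth()` — additionally population 3's ATAC profiles are replaced
  by population-2 profiles: each view confuses a different pair and only
  the joint analysis recovers all three groups.
* `addDropout(p)` — each entry of each view is zeroed independently with
  probability $p$; from 65% baseline sparsity, $p = 0.5/0.7/0.9$ lands
  at 82/90/96%.
* `rarePopulation()` — one population is downsampled to 10 cells.

What the generator does *not* emulate: real library-size variation,
batch effects, doublets, ambient contamination, the heavy-tailed
feature-count distributions of real scATAC data, or any correlation
structure beyond the shared population programs. Tests passing on these
data demonstrate the mechanics of the method (complementarity across
views, sparsity control, robustness of the metrics), not performance on
real tissues.

## Evaluation metrics

* `ariScore()` — adjusted Rand index via the contingency-table closed
  form (cross-checked in the tests against an independent
  implementation); about 0 for independent partitions, 1 for identical.
* `ariAcrossResolutions()` — Leiden clustering (modularity, seeded) on
  the euclidean kNN graph ($k = 20$) of embedding columns over a
  resolution grid (default 0.1–2.0 in steps of 0.1; the grid is a
  package decision), reporting the curve and its maximum. For
  three-population data high resolutions necessarily overcluster, so the
  maximum is the headline number.
* `silhouetteScore()` — mean silhouette width on euclidean distances.
* `knnPurity()` — average fraction of a cell's $k = 20$ nearest
  neighbours sharing its label (self excluded, distance ties broken by
  index). The neighbourhood size mirrors the clustering graph; the
  source text leaves purity's $k$ unstated.
* `specificityTable()` — for every factor $i$ and cell type: the
  fraction of in-type cells with $|w| > 10^{-3}$ (reported but not used
  in the score), the mean weight inside ($a_i$) and outside ($b_i$) the
  type, and $\mathrm{specificity}_i = (a_i - b_i)/\max_j a_j \le 1$.
  Models with signed factors are split into positive and negative parts
  first; simplex models are unaffected.

## Interpretation exports

`exportInterpretation()` writes, per modality, the inputs downstream
enrichment tools consume: per-factor ranked gene lists (top 150 after
row-normalizing the dictionary; enrichment tools typically treat the
list as unordered — the ranking is for inspection), per-factor BED3
files of top 100 peaks plus the union-of-tops background BED (peak ids
`chrom:start-end`, 1-based inclusive, converted to 0-based half-open
BED — the coordinate convention is a package decision and is stated in
the docs), and per-factor top-protein TSVs. Downstream gene-set
selection conventionally keeps terms with Bonferroni-adjusted p-values
below 0.05; running the enrichment itself is out of scope. Exports are
pure functions of the model and reproduce byte-identically.

## Baseline

`integrativeNMF()` concatenates the features of all views and minimizes
$\|A - HW\|$ under nonnegativity by multiplicative updates ($10^{-10}$
denominator guard, objective non-increasing, deterministic given the
seed, default $k = 30$); $H$ columns are L2-normalized after the fit as
a reporting convention. This is the Euclidean baseline the transport
model is compared against, essentially the feature-concatenation variant
of integrative NMF with equal view weights.

## Problem sizes and degenerate inputs

The reference analyses in the tests and the acceptance script run at
desk scale, chosen once: controlled-setting fits use $3 \times 50$
cells with 80 selected features per view and $k = 5$ (15 outer
iterations); the sparsity-control sweep uses $3 \times 15$ cells, 30
features per view, $k = 5$; optimizer-correctness checks use
$m \le 5$, $n \le 4$ instances against brute-force and LP oracles.
Degenerate inputs are rejected with informative errors: all-zero cells
(normalization, simplex projection), zero-norm features (cost
construction drops them with a warning, or errors on request), histogram
sums off by more than $10^{-6}$, cell types with zero members, $k = 1$,
and ground costs larger than the memory budget. Non-converged Sinkhorn
runs warn with the achieved marginal violation rather than failing
silently.

## Known limitations

* No out-of-sample projection of new cells, no mini-batching: each fit
  is a full batch optimization.
* Costs are dense $m_p \times m_p$ matrices; feature selection is the
  intended way to keep them small (a memory guard enforces this).
* No batch correction: the model assumes one batch per dataset.
* The alternating scheme converges to a block-coordinate stationary
  point of a non-convex problem; different seeds can reach different
  (typically equivalent up to factor permutation) solutions.
* The number of latent dimensions is problem-dependent; classical NMF
  model-selection tools (cophenetic coefficient, elbow) apply.
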