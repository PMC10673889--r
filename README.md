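# otOmics

Joint factorization of **paired single-cell multi-omics data** — any
number of modalities (RNA, chromatin accessibility, surface proteins)
measured in the *same* cells — into omic-specific nonnegative
dictionaries and one shared cell embedding, with an **entropy-regularized
optimal-transport** reconstruction loss.

It is written for computational biologists who have paired matrices
(10X Multiome, CITE-seq, TEA-seq, scCAT-seq, ...) and want a
low-dimensional cell embedding that uses the complementary information of
all modalities, together with directly interpretable per-modality factor
loadings.

## The model

Given views $A^{(p)} \in \mathbb{R}_+^{m_p \times n}$ with columns
normalized to the probability simplex, otOmics solves

$$
\min_{H^{(p)},\, W}\;\; \sum_p \Big( \sum_{j=1}^n
\mathrm{OT}_\varepsilon\big(H^{(p)} w_j,\; a^{(p)}_j\big)
\;-\; \rho_p\, E(H^{(p)}) \;-\; \mu\, E(W) \Big)
$$

with $H^{(p)} \in \mathbb{R}_+^{m_p \times k}$, shared
$W \in \mathbb{R}_+^{k \times n}$, all columns on the simplex.
$\mathrm{OT}_\varepsilon$ is entropic optimal transport over the cosine
ground cost between features, so reconstruction error can flow between
similar features instead of being charged coordinate-wise; the entropy
penalties control sparsity through the scaled coldness parameters
$\rho_p = \tilde\rho_p / (\log(m_p) k)$ and
$\mu = \tilde\mu / (\log(k) n)$. Optimization alternates smooth Fenchel
duals solved by L-BFGS, with softmax recovery of the simplex-constrained
primals. See the methods vignette
(`vignettes/otOmics-methods.Rmd`) for the full derivation, defaults and
numerical choices.

The package also ships the per-modality preprocessing recipes
(lognorm / TF-IDF / CLR + variable-feature selection + simplex
projection), an integrative-NMF baseline, a synthetic three-population
generator with controlled-setting transformations (mixed profiles, extra
dropout, rare population), clustering/embedding metrics (silhouette, ARI
across Leiden resolutions, kNN purity, factor specificity) and
loading-based interpretation exports (ranked gene lists, BED3 peak sets,
protein tables).

## Worked example

```r
library(otOmics)

# three cell populations, two omics, 150 shared cells, 65% sparse;
# population 1's RNA is replaced by population-2 profiles, so RNA alone
# cannot separate them
ds  <- simulateMultiOmics(seed = 1)
ds  <- mixInRNA(ds, seed = 2)
dsp <- preprocessDataset(ds, nTopRNA = 80, nTopATAC = 80)

truth <- cellLabels(dsp)

# RNA alone merges populations 1 and 2
rna <- as.matrix(viewMatrix(getView(dsp, "rna")))
ariAcrossResolutions(rna, truth, seed = 1)$maxARI
#> [1] 0.568

# the joint factorization separates all three populations
fit <- fitFactorModel(dsp, modelConfig(k = 5, seed = 1, outerMaxIter = 15))
ariAcrossResolutions(embedding(fit), truth, seed = 1)$maxARI
#> [1] 0.941
```

The first number (0.568) is the ceiling for any clustering of the
scrambled RNA view: populations 1 and 2 are copies of each other there,
and merging two of three equal groups caps the adjusted Rand index at
0.568. The joint embedding recovers the three planted populations
(max ARI 0.941 across Leiden resolutions), because the untouched
chromatin view disambiguates the two populations that RNA confuses —
exactly the complementarity the shared embedding is built to exploit.

Factor loadings are exported for downstream enrichment:

```r
exportInterpretation(fit, "interpretation/")   # ranked genes, BED3 peaks
```

A thin command-line wrapper with `simulate`, `preprocess`, `fit`,
`fit-baseline`, `evaluate`, `interpret` and `run` subcommands is
installed at `inst/scripts/otomics`; `runPipeline()` drives the same
stages from one YAML configuration and writes a manifest for
reproducibility.

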