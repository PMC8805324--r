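# mudkit

Multimodal omics containers for R, with a language-agnostic HDF5
serialisation (`.h5mu`), per-modality preprocessing, and cross-modality
integration.

## The problem

Multimodal single-cell designs profile several assays on the same cells —
gene expression plus chromatin accessibility (10x multiome), gene
expression plus surface-protein epitopes (CITE-seq), and beyond. Analysing
them requires three things that single-omics toolkits do not provide:

1. a **container** that holds several annotated matrices over a shared
   cell axis while tolerating cells missing from some assays, with
   subsetting, annotation push/pull and derived-data slots that stay
   consistent across modalities;
2. an **exchange format** readable from any language, in which each
   modality remains independently accessible and metadata can be read
   without loading count matrices from disk;
3. **integration methods** that combine modalities: per-cell weighted
   fusion of neighbour graphs, and joint factorisation with a per-modality
   variance decomposition.

mudkit implements all three for R users (analysts working with multiome /
CITE-seq data, and tool authors who need a stable on-disk contract), plus
seeded synthetic generators so every stage is testable without downloads.

## The core model

A `MuContainer` maps a global cell axis (ordered union of per-modality
cells) and a global feature axis (concatenation of per-modality features)
onto each modality through integer *axis maps* (`0` = absent, `k` = local
position `k`, order-preserving). On disk this becomes a self-describing
HDF5 hierarchy (`mod/<name>/{X, obs, var, layers, obsm, ...}` per
modality, global slots and axis maps at the root) with dense matrices as
2-D datasets, sparse matrices as CSR triplet groups, and annotation tables
as typed column groups with explicit missing-value codes.

Integration follows the weighted-nearest-neighbour scheme for *M ≥ 2*
modalities: per modality, within- and cross-modality predictions of each
cell's embedding are scored by an adaptive kernel
`exp(-max(d − d1, 0)/max(σ − d1, ε))`; per-cell modality weights are the
softmax of within/cross affinity ratios; the fused graph keeps the top
neighbours under the weight-averaged kernel `a(i,j) = Σ_m w_m(i)·c_m(i,j)`.
Joint factorisation is a deterministic SVD of the feature-concatenated
(optionally scale-balanced) blocks: factors `Z = UD`, loadings `W_m`, and
variance explained `r²[m,k] = ‖z_k w_mkᵀ‖²_F / ‖X_m‖²_F`, separating
shared from modality-specific factors. Preprocessing covers library-size
log-normalisation, scaling, binned-dispersion feature selection,
TF-IDF/LSI for accessibility, and background-based denoising of epitope
counts (z-scoring against empty droplets, then removal of a per-cell
technical factor estimated by a guarded two-component Gaussian mixture).

See `vignettes/multimodal-analysis.Rmd` for the methods in full, including
every default and the reasoning behind the estimator guards.

## Worked example

```r
library(mudkit)

# paired RNA + ATAC with 3 cell groups driven by shared latent factors
mc <- simulate_multiome(sim_params(n_cells = 300, n_groups = 3, seed = 1))
mc
#> MuContainer  300 obs x 500 var, 2 modalities
#>   mod 'rna': 300 x 200
#>   mod 'atac': 300 x 300
#>   uns: truth

# per-modality preprocessing into layers
mc$mod$rna$layers$lognorm <- normalize_total_log1p(mc$mod$rna$X)
mc$mod$atac$layers$tfidf  <- tfidf(mc$mod$atac$X)
rna_s  <- scale_center(mc$mod$rna$layers$lognorm)
atac_s <- scale_center(as.matrix(mc$mod$atac$layers$tfidf))

# joint factorisation with per-modality variance decomposition
fit <- joint_factor_svd(list(rna = rna_s, atac = atac_s), n_factors = 4)
round(fit$r2, 3)
#>       [,1]  [,2]  [,3]  [,4]
#> rna  0.155 0.123 0.080 0.038
#> atac 0.175 0.126 0.079 0.004

# weighted nearest neighbours over per-modality PCA embeddings
w <- wnn(list(rna = pca(rna_s, 20)$coords, atac = pca(atac_s, 20)$coords), k = 20)
round(colMeans(w$weights), 3)
#> [1] 0.508 0.492

# serialise and inspect without loading counts
write_h5mu(mc, "pbmc_sim.h5mu")
cmd_info("pbmc_sim.h5mu")
#> pbmc_sim.h5mu  (encoding-version 0.1.0)
#> MuData: 300 obs x 500 var, 2 modalities
#>   mod/rna: 300 x 200 (dense)  layers: lognorm
#>   mod/atac: 300 x 300 (csr)  layers: tfidf
#>   uns: truth
```

Reading the numbers: the `r2` table decomposes each modality's variance
over the four factors — factors 1–3 are shared (similar shares in both
assays) while factor 4 is RNA-specific (0.038 vs 0.004), matching the
generator's design of one RNA-only factor. The WNN weights average close
to 0.5/0.5 because both modalities here carry the same group structure;
on a simulation where one modality is pure noise the informative modality's
mean weight exceeds 0.95. The file report shows the dense RNA matrix and
the CSR-encoded accessibility matrix with their preprocessing layers.

A command-line launcher for inspection, validation, subsetting, export and
simulation is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "mudkit", package = "mudkit"))')" \
    info pbmc_sim.h5mu
```

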