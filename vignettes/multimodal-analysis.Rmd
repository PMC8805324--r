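---
title: "Multimodal containers, .h5mu serialisation and integration methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal containers, .h5mu serialisation and integration methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mudkit)
```

mudkit organises multimodal omics experiments — the same cells profiled on
several assays, e.g. gene expression plus chromatin accessibility
(multiome) or gene expression plus surface-protein epitopes (CITE-seq) —
as a single container, serialises it to a language-agnostic HDF5 dialect,
and provides the per-modality preprocessing and cross-modality integration
steps that such designs call for. This vignette explains the data model,
the numerical methods, the choices behind their defaults, and what the
synthetic generators do and do not emulate.

## The container model

An `AnnotatedMatrix` holds one modality: a primary cells × features matrix
`X` (dense or compressed-sparse-row), annotation tables `obs` and `var`
indexed by unique names, and named auxiliary slots (`layers` for
transformed matrices, `obsm`/`varm` for per-axis embeddings,
`obsp`/`varp` for pairwise graphs, `uns` for unstructured metadata).

A `MuContainer` is an ordered collection of named modalities sharing two
*global* axes:

* **observations** — the union of the modalities' cell names, in
  first-seen order scanning modalities in insertion order. A cell may be
  measured in only a subset of the assays; nothing forces the modalities
  to agree.
* **features** — the concatenation of the modalities' feature names in
  modality order. Feature names are expected to be disjoint across
  modalities; when they collide, the colliding entries are prefixed
  `"modality:"` *in the global table only*, so every modality subtree
  remains standalone-readable under its own local names. (Whether the
  global feature axis should union or concatenate colliding names is a
  genuinely open design point; concatenation-with-prefix was chosen
  because it never merges features that merely share an identifier.)

Each modality is tied to the global axes by an integer **axis map**: entry
`k > 0` says "global element *g* is local row *k*", `0` marks absence. Two
invariants are maintained: the nonzero entries of a map are exactly a
permutation of the local axis, and they appear in increasing order. The
second invariant is not automatic — two modalities could list shared cells
in different orders — so `mu_update()` stably reorders each modality's
rows into global order. This makes every map a monotone enumeration, which
in turn makes subsetting semantics unambiguous and lets the on-disk maps
be validated without reference to the cell names.

Mutating the modality list (`set_modality()`, `del_modality()`) does *not*
recompute global axes; the container is flagged stale and axis-dependent
operations refuse to run until `mu_update()`. This keeps mutation O(1) and
makes the recomputation point explicit rather than hidden inside every
accessor.

`mu_update()` also pulls every modality annotation column into the global
table under `"modality:column"`, with missing values where a cell is
absent from that modality; user-added global columns are preserved across
updates for surviving names. `push_obs()`/`pull_obs()` move columns the
other way on demand.

`subset()` takes selectors over the *global* axes (masks, positions or
names; unknown names and duplicates are rejected). Observations follow the
selector's order; each modality keeps exactly its members among the
selected elements; features are regrouped into per-modality blocks so the
concatenation invariant survives. Modalities emptied by a selection are
kept as zero-row (or zero-column) modalities rather than dropped, so
round-trips through selections never change the modality list.

## The .h5mu dialect

`write_h5mu()` produces a self-describing HDF5 file: root attributes
`encoding-type = "MuData"`, `encoding-version` (currently `0.1.0`; readers
accept any file of the same major version) and `generator`; a `mod` group
with a `mod-order` attribute and one AnnData-layout subtree per modality;
and top-level `obs`, `var`, `obsm`, `varm`, `obsp`, `varp`, `uns`,
`obsmap`, `varmap`. Axis maps are stored with the in-memory convention:
1-based local positions, `0` for absent.

Encodings:

* dense matrices are 2-D datasets stored so that their C-order
  (observation-major) shape is cells × features — the convention used by
  the Python single-cell stack, verified in the test suite by decoding
  files with h5py;
* sparse matrices are groups with `encoding-type = "csr_matrix"`, a
  `shape` attribute and `data`/`indices`/`indptr` datasets (0-based,
  row-sorted). Column-compressed input is converted to row-compressed
  form on write: one canonical on-disk layout keeps the validator and
  every foreign reader simple;
* annotation tables are groups with `encoding-type = "dataframe"`,
  `_index` and `column-order` attributes; categorical columns are
  `{codes, categories}` subgroups with `-1` as the missing code;
  logical columns are int8 datasets tagged `boolean` (`-1` missing);
  strings are variable-length UTF-8. Integer columns containing missing
  values are stored as floats (NaN at the gaps) tagged `integer` so the
  reader restores the dtype exactly. String columns with missing values
  are rejected at write time — there is no portable HDF5 encoding for
  them short of inventing a mask dataset; categorical columns are the
  supported carrier for nullable labels;
* `uns` accepts scalars, numeric/string/logical arrays, matrices and
  named lists (nested groups); anything else is rejected with the full
  key path, keeping the format language-agnostic.

Writes are atomic (temp file + rename) and deterministic in iteration
order; datasets above 64 KiB are gzip-compressed at level 4 (configurable)
so small test files stay inspectable with `h5dump`. Because HDF5 groups
carry no insertion order, named slots (`layers`, `obsm`, `uns`, …) are
treated as unordered maps throughout, and the deep-equality comparator
used for round-trip checks compares them by name.

`read_h5mu(path, backed = TRUE)` loads all annotations, maps, embeddings
and metadata but replaces each `X` and layer with an `H5BackedMatrix`
handle that knows its shape and storage kind and reads matrix content only
when sliced or materialised. Every dataset read inside the package goes
through an instrumented channel (`h5_read_stats()`), which is how the
tests prove that metadata access — including `cmd_info()` and
`cmd_validate()` — touches zero count data.

`validate_h5mu()` checks the layout rules and the axis-map invariants. The
default pass reads only structural metadata and the (small) axis maps, so
it honours the backed contract; `deep = TRUE` additionally reads sparse
index arrays to verify index range and per-row sortedness.

## Per-modality preprocessing

* `normalize_total_log1p(X, scale_factor = 1e4)` — rows scaled to a
  common total then `log1p`. The target of $10^4$ is the prevailing
  convention for single-cell counts. Zero rows pass through unchanged and
  zeros stay zeros, so sparsity is preserved.
* `scale_center(X, max_value = 10)` — columns centred and scaled to unit
  *population* standard deviation (population moments are used everywhere
  in the package for consistency), zero-variance columns become zeros,
  and values are clipped at ±10 — the customary guard against a handful
  of extreme cells dominating downstream decompositions.
* `select_hvf(X, n_top, n_bins = 20)` — per-feature dispersion
  (variance/mean) z-scored within 20 equal-count bins of mean expression,
  top `n_top` by z-score, ties broken toward the lower feature index.
  Bins that collapse (singleton or tied dispersions) fall back to
  z-scoring against the global dispersion distribution; without this an
  isolated high-dispersion feature sitting alone in the top mean bin
  would receive z = 0 and could never be selected.
* `tfidf(X, scale_factor = 1e4)` — the accessibility reweighting with
  term frequency = row proportion, inverse document frequency =
  $n/\mathrm{df}$, output $\log(1 + \mathrm{TF}\cdot\mathrm{IDF}\cdot
  10^4)$. Several TF-IDF variants circulate in the ATAC literature; this
  one is fixed as normative here. It is scale-free per cell (doubling a
  cell's counts leaves its row unchanged) and zero-preserving.
* `lsi(X, n_comps, drop_first)` — truncated SVD of the uncentred TF-IDF
  matrix with a deterministic sign convention (largest-|loading| entry of
  each component positive, the same convention as `pca()`). The first
  component of an LSI decomposition correlates almost perfectly with log
  total counts (the tests measure |r| > 0.9 on simulated accessibility
  data), which is why `drop_first` exists.

## Epitope denoising (dsb-style)

Protein counts from droplet assays mix real signal with an ambient
background that is directly measurable in cell-free droplets, plus a
per-cell technical factor (capture/amplification efficiency). The
normalisation proceeds in the standard two stages:

1. `log1p` both matrices; z-score each protein in the cells against the
   empty-droplet mean and population sd (sd floored at $10^{-3}$);
2. estimate a per-cell technical factor $\lambda_i$ from the cell's
   protein z-score vector and return $z_{ij} - \lambda_i$.

$\lambda_i$ is the mean of the background component of a two-component
univariate Gaussian mixture fit by EM (at most 500 iterations or a
log-likelihood change below $10^{-8}$). Three estimator details are the
package's own design, chosen because the naive mixture is badly behaved
on realistic panels:

* **Initialisation** is the optimal 1-D two-cluster partition of the
  vector (an exact threshold scan minimising within-cluster sum of
  squares), not fixed percentiles. With a 30-protein panel and only a
  couple of positive markers, percentile-based starting means both land
  inside the background bulk and EM frequently never discovers the
  positive component. The scan is deterministic and shift-equivariant,
  which keeps the removal of a per-cell shift exact.
* **Model selection**: the 2-component fit is accepted only if its ICL
  (BIC plus the assignment-entropy penalty, the criterion used by
  model-based clustering) beats a single Gaussian; otherwise
  $\lambda_i$ is the plain mean. A cell with no positive proteins has a
  unimodal z-vector, and an unconditional 2-component fit straddles it —
  the "lower component mean" is then biased by almost a full background
  sd. A variance floor of $0.01$ on the z-scale additionally blocks
  degenerate spike components.
* **Majority rule**: the background is, by assumption, the majority of
  the panel. If the accepted mixture's lower component holds less than
  half the proteins it is a left tail of the discrete count distribution,
  not a background-versus-positive split, and the dominant component's
  mean is used instead.

With these guards the tests verify: empty droplets standardise to
per-protein mean 0, sd 1; simulated pure-background cells come out centred
(per-protein |mean| < 0.1 at 2000 cells — at much smaller n the
per-protein sampling error alone exceeds that bound); adding a constant to
one cell's z-vector shifts $\lambda$ by exactly that constant and leaves
the output unchanged; and group markers stay separated by > 3 background
sd. No isotype-control step is included (the panel abstraction here has
none), and $\lambda$-subtraction is used rather than the per-protein
regression of the original method — subtraction preserves exact per-cell
shift equivariance, at the cost of not forcing each protein's overall
mean to zero.

## Multimodal integration

`pca(X, n_comps)` is the SVD of the column-centred matrix with the
deterministic sign convention; explained-variance ratios are squared
singular values over the total variance.

`knn(coords, k)` computes exact Euclidean k nearest neighbours (brute
force; approximate search is out of scope at the intended problem sizes),
ties broken toward the lower index, and converts distances to
connectivities with a per-cell adaptive kernel
$c(i,j) = \exp\!\big(-\max(d_{ij} - d^{(1)}_i, 0) / \max(\sigma_i -
d^{(1)}_i, \varepsilon)\big)$ where $d^{(1)}_i$ and $\sigma_i$ are the
first and k-th neighbour distances and $\varepsilon = 10^{-6}$ guards
duplicated points; the matrix is symmetrised by the elementwise maximum.
Each cell's nearest neighbour has connectivity exactly 1.

`wnn(embeddings, k = 20, k_out = 20)` fuses an arbitrary number of
modalities. For each modality $m$ the within-prediction of cell $i$ is the
average of $E_m$ over $i$'s neighbours in $E_m$, the cross-prediction the
average over its neighbours in another modality $E_{m'}$. Prediction
errors pass through the same adaptive kernel (with
$\varepsilon = 10^{-4}$) to give affinities $\theta_{m\leftarrow m'}(i)$;
the ratio $s_m(i) = \theta_{m\leftarrow m} / (\operatorname{mean}_{m'\ne
m}\theta_{m\leftarrow m'} + \varepsilon)$ measures how much better
modality $m$ predicts itself than the other modalities predict it, and
per-cell weights are the softmax of these ratios over modalities. The
arithmetic mean over the other modalities is the symmetric choice that
reduces to the two-modality form at $M = 2$; softmax (rather than
proportional normalisation) is normative here. The fused affinity
$a(i,j) = \sum_m w_m(i)\,c_m(i,j)$ keeps the `k_out` strongest partners
per cell (ties toward the lower index); because the fused graph is
affinity-ranked, its `distances` slot stores $1 - a \in [0, 1)$.
Two byte-identical embeddings receive weights of exactly $1/M$, and a
loop-level transcription of these formulas is kept in the test suite as an
independent oracle (agreement to $10^{-10}$).

`joint_factor_svd(mc, n_factors, balance)` is a deterministic joint
factorisation: the preprocessed modality blocks are concatenated along
features (optionally divided by their top singular value so no modality
dominates by scale) and decomposed by truncated SVD; $Z = UD$,
per-modality loadings are the corresponding rows of $V$, and the variance
explained by factor $k$ in modality $m$ is the *marginal*
$r^2_{mk} = \lVert z_k w_{mk}^\top\rVert_F^2 / \lVert X_m\rVert_F^2$
(marginal rather than sequential shares; with orthogonal factors they sum
to at most 1 per modality). This is an interface-compatible, reproducible
stand-in for probabilistic multi-omics factor models — it recovers shared
versus modality-specific factors on data that match its linear
assumptions, but performs no automatic relevance determination, handles no
missing observations and models no non-Gaussian likelihoods. Input is
expected to be scaled already; no centring is applied, which is what makes
the single-modality unbalanced case coincide exactly with PCA on centred
input.

Nonlinear embedding (UMAP and friends) is consumed through the
`fused_umap()` adapter: the package hands a connectivity matrix to an
externally supplied embedder and stores the returned coordinates under
`obsm[["X_umap"]]`; without an embedder it raises a capability error
rather than approximating one.

## Synthetic data

The generators produce containers with the statistical structure the
analyses assume, so the whole stack is testable without downloads.

`simulate_multiome()` draws cell groups, builds a latent factor matrix
`Z`, and emits RNA counts as
$\mathrm{Poisson}\big(\mathrm{softplus}(Z W_\mathrm{rna}^\top + b)\cdot
s_i\big)$ with log-normal size factors $s_i$
(`depth_lognormal_sigma = 0.3`), and binary accessibility as
$\mathrm{Bernoulli}\big(\sigma(Z W_\mathrm{atac}^\top + b')\big)$ with
negative peak offsets for realistic sparsity, stored row-sparse. Two
latent design choices matter:

* factor columns are **whitened** (exactly uncorrelated, unit sd) and
  then given strictly decreasing strengths (2.5 down to 1). These are the
  standard identifiability assumptions of factor models — without
  distinct, uncorrelated factor variances a factorisation can only
  recover the latent subspace, not individual axes, and parameter
  recovery would be ill-posed regardless of implementation;
* the **last factor loads only on RNA**, providing a modality-specific
  factor whose variance-explained ratio between modalities the tests
  check (measured ratio ≈ 15 at n = 500).

Group structure (not continuous trajectories) is used throughout: the
acceptance checks need separability, nothing more. Ground truth (`Z`,
loadings, labels, size factors) is stored in `uns`/`obs`.

`simulate_citeseq()` adds a protein modality: negative binomial counts
(dispersion 10) around per-protein ambient means (log-normal around 15,
the scale of typical antibody panels), two marker proteins per group
amplified 12-fold in their group, and a per-cell log-normal capture factor
(sd 0.25) multiplying all of a cell's protein rates — the technical
component the denoising step must remove. Empty droplets are drawn from
the ambient component alone.

`drop_cells_per_modality()` removes a seeded fraction of cells
independently per modality, exercising the union semantics.

What the generators deliberately do **not** emulate: batch effects,
doublets, realistic marker panels or peak annotations, fragment-level
accessibility, continuous differentiation trajectories, isotype controls.
Green tests therefore demonstrate correctness of the algorithms under the
stated generative assumptions — linear latent structure, group
separability, shared ambient background — not robustness to the full
messiness of real experiments.

## Problem sizes and numerical conventions

The test and verification workloads run at desk scale, chosen so the whole
suite completes in well under a minute of compute per module: round-trip
and subsetting checks on containers of 4–12 cells across 1–3 modalities
(25 and 100 seeded cases), neighbour and weighting oracles at n = 30–300,
factor recovery at n = 500 cells with 200 genes and 300 peaks, denoising
at 400 cells, 30 proteins and 5000 empty droplets. Determinism rules
used throughout: population (ddof 0) standard deviations; ties broken
toward the lower index; SVD signs fixed by the largest-|loading| entry;
every stochastic step seeded explicitly. Degenerate inputs are defined
rather than accidental: zero count rows stay zero, constant columns scale
to zeros, duplicated points get unit connectivity through the
$\varepsilon$ floors, empty intersections yield valid zero-observation
containers with a warning.

## Known limitations

Backed mode is read-only and materialises slices through row ranges (no
partial writes or appends); Zarr and cloud backends are out of scope. The
joint factorisation is linear and complete-case. Exact kNN is quadratic in
cells. The CLI surfaces inspection, validation, subsetting, export and
simulation but deliberately no plotting or server mode. Feature-relation
graphs across modalities (`varp`) are stored and round-tripped but no
graph algorithms operate on them.
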