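#' Principal component analysis of a single modality
#'
#' Singular value decomposition of the column-centred matrix, with a
#' deterministic sign convention (largest-magnitude loading of each
#' component positive). Explained variance ratios are squared singular
#' values over the total variance of the centred matrix.
#'
#' @param X finite matrix, observations in rows.
#' @param n_comps number of components (`< min(n, d)`).
#' @return An `Embedding`: `coords` (`n x K` scores), `loadings`
#'   (`d x K`), `explained_variance_ratio` (non-increasing, sums to <= 1).
#' @export
pca <- function(X, n_comps) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite")
  if (n_comps >= min(dim(X)))
    stop(sprintf("n_comps = %d must be < min(n, d) = %d", n_comps, min(dim(X))))
  Xc <- sweep(X, 2L, colMeans(X), "-")
  sv <- svd(Xc)
  total <- sum(sv$d^2)
  d <- sv$d[seq_len(n_comps)]
  u <- sv$u[, seq_len(n_comps), drop = FALSE]
  v <- sv$v[, seq_len(n_comps), drop = FALSE]
  for (k in seq_len(n_comps)) {
    piv <- which.max(abs(v[, k]))
    if (v[piv, k] < 0) { v[, k] <- -v[, k]; u[, k] <- -u[, k] }
  }
  structure(list(coords = u %*% diag(d, n_comps),
                 loadings = v,
                 explained_variance_ratio = if (total > 0) d^2 / total else rep(0, n_comps)),
            class = "Embedding")
}

#' Exact k-nearest-neighbour graph with adaptive-bandwidth connectivities
#'
#' Brute-force Euclidean k nearest neighbours (ties broken toward the
#' lower index). Connectivities use a per-cell adaptive kernel:
#' `c(i,j) = exp(-max(d(i,j) - d1_i, 0) / max(sigma_i - d1_i, eps))`
#' where `d1_i` and `sigma_i` are the distances to the 1st and k-th
#' neighbour of `i`; the matrix is symmetrised by the elementwise
#' maximum. Every cell's nearest neighbour has connectivity exactly 1.
#'
#' @param coords `n x d` embedding matrix.
#' @param k number of neighbours (`k < n`).
#' @param eps bandwidth floor guarding duplicated points.
#' @return A `NeighborGraph`: `indices` (`n x k`), `distances` (`n x k`,
#'   row-sorted ascending), `connectivities` (sparse symmetric `n x n`,
#'   values in `(0, 1]`).
#' @export
knn <- function(coords, k, eps = 1e-6) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k >= n) stop(sprintf("k = %d must be < n = %d", k, n))
  D <- as.matrix(stats::dist(coords))
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))      # ties toward the lower index
    ord <- ord[ord != i][seq_len(k)]
    idx[i, ] <- ord
    dst[i, ] <- D[i, ord]
  }
  d1 <- dst[, 1L]
  sigma <- dst[, k]
  C <- matrix(0, n, n)
  for (i in seq_len(n))
    C[i, idx[i, ]] <- exp(-pmax(dst[i, ] - d1[i], 0) / max(sigma[i] - d1[i], eps))
  C <- pmax(C, t(C))
  structure(list(indices = idx, distances = dst,
                 connectivities = methods::as(Matrix::Matrix(C, sparse = TRUE), "CsparseMatrix")),
            class = "NeighborGraph")
}

#' Weighted nearest neighbours across an arbitrary number of modalities
#'
#' Fuses per-modality embeddings into a single neighbour graph with
#' per-cell modality weights, following the within- versus
#' cross-modality prediction scheme. For each modality `m` with
#' embedding `E_m` and its k-nearest-neighbour sets:
#'
#' * within-prediction: the average of `E_m` over cell `i`'s neighbours
#'   in modality `m`; cross-prediction: the average of `E_m` over `i`'s
#'   neighbours in another modality `m'`;
#' * prediction affinities
#'   `theta(i) = exp(-max(||E_m(i) - p|| - d1_m(i), 0) / max(sigma_m(i) - d1_m(i), eps))`
#'   with `d1`/`sigma` the 1st/k-th neighbour distances in `E_m`;
#' * the affinity ratio `s_m(i)` is the within affinity over the mean of
#'   the cross affinities from the other modalities (plus `eps`), and
#'   the weights are the softmax of the ratios over modalities;
#' * the fused affinity to any cell `j` is the weight-averaged
#'   per-modality kernel
#'   `a(i,j) = sum_m w_m(i) exp(-max(d_m(i,j) - d1_m(i), 0) / max(sigma_m(i) - d1_m(i), eps))`,
#'   of which the `k_out` largest per cell are kept (ties toward the
#'   lower index).
#'
#' @param embeddings list of `M >= 2` coordinate matrices sharing rows
#'   (same cells, same order).
#' @param k neighbours per modality for bandwidths and predictions.
#' @param k_out neighbours retained in the fused graph.
#' @param eps affinity floor (also guards degenerate bandwidths).
#' @return A `WnnResult`: `weights` (`n x M`, rows on the simplex),
#'   `graph` (a `NeighborGraph` under the fused affinity, with
#'   `distances = 1 - affinity`), `bandwidths` (per-modality `d1`,
#'   `sigma`).
#' @export
wnn <- function(embeddings, k = 20L, k_out = 20L, eps = 1e-4) {
  M <- length(embeddings)
  if (M < 2L) stop("at least two modalities are required")
  embeddings <- lapply(embeddings, as.matrix)
  n <- nrow(embeddings[[1L]])
  for (m in seq_len(M)) {
    if (nrow(embeddings[[m]]) != n)
      stop("all embeddings must share the same observations (row counts differ)")
    if (all(apply(embeddings[[m]], 2L, stats::sd) == 0))
      stop(sprintf("embedding %d has zero variance (degenerate bandwidths)", m))
  }
  if (k >= n) stop(sprintf("k = %d must be < n = %d", k, n))

  Dm <- lapply(embeddings, function(E) as.matrix(stats::dist(E)))
  nn <- vector("list", M); d1 <- matrix(0, n, M); sigma <- matrix(0, n, M)
  for (m in seq_len(M)) {
    g <- knn_from_dist(Dm[[m]], k)
    nn[[m]] <- g$indices
    d1[, m] <- g$distances[, 1L]
    sigma[, m] <- g$distances[, k]
  }

  # theta[[m]][, m2]: affinity of modality-m representation predicted
  # from modality-m2 neighbourhoods
  theta <- lapply(seq_len(M), function(m) matrix(0, n, M))
  for (m in seq_len(M)) {
    E <- embeddings[[m]]
    for (m2 in seq_len(M)) {
      pred <- nn_average(E, nn[[m2]])
      derr <- sqrt(rowSums((E - pred)^2))
      theta[[m]][, m2] <- exp(-pmax(derr - d1[, m], 0) / pmax(sigma[, m] - d1[, m], eps))
    }
  }
  s <- sapply(seq_len(M), function(m) {
    cross <- rowMeans(theta[[m]][, -m, drop = FALSE])
    theta[[m]][, m] / (cross + eps)
  })
  w <- exp(s - apply(s, 1L, max))
  w <- w / rowSums(w)

  # fused affinity over all pairs, top k_out per cell
  A <- matrix(0, n, n)
  for (m in seq_len(M)) {
    bw <- pmax(sigma[, m] - d1[, m], eps)
    A <- A + w[, m] * exp(-pmax(Dm[[m]] - d1[, m], 0) / bw)
  }
  diag(A) <- 0
  idx <- matrix(0L, n, k_out); aff <- matrix(0, n, k_out)
  for (i in seq_len(n)) {
    ord <- order(-A[i, ], seq_len(n))
    ord <- ord[ord != i][seq_len(k_out)]
    idx[i, ] <- ord
    aff[i, ] <- A[i, ord]
  }
  C <- matrix(0, n, n)
  for (i in seq_len(n)) C[i, idx[i, ]] <- aff[i, ]
  C <- pmax(C, t(C))
  graph <- structure(
    list(indices = idx, distances = 1 - aff,
         connectivities = methods::as(Matrix::Matrix(C, sparse = TRUE), "CsparseMatrix")),
    class = "NeighborGraph")
  structure(list(weights = w, graph = graph,
                 bandwidths = list(d1 = d1, sigma = sigma)),
            class = "WnnResult")
}

knn_from_dist <- function(D, k) {
  n <- nrow(D)
  idx <- matrix(0L, n, k); dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))
    ord <- ord[ord != i][seq_len(k)]
    idx[i, ] <- ord
    dst[i, ] <- D[i, ord]
  }
  list(indices = idx, distances = dst)
}

nn_average <- function(E, idx) {
  out <- matrix(0, nrow(E), ncol(E))
  k <- ncol(idx)
  for (j in seq_len(k)) out <- out + E[idx[, j], , drop = FALSE]
  out / k
}

#' Joint factorisation of a multimodal container with variance decomposition
#'
#' A deterministic multi-omics factor model: the preprocessed modality
#' matrices are concatenated along features (optionally balanced by
#' dividing each block by its top singular value) and decomposed by
#' truncated SVD. Factors `Z = U D` have orthogonal columns; per-modality
#' loading blocks `W_m` are the corresponding rows of `V`. The variance
#' explained by factor `k` in modality `m` is the marginal
#' `r2[m,k] = ||z_k w_mk'||_F^2 / ||X_m||_F^2`, which distinguishes
#' factors shared across omics from modality-specific ones.
#'
#' All modalities must share all observations; run [intersect_obs()]
#' first if cells are missing from some modalities. Matrices are expected
#' to be preprocessed (e.g. [scale_center()]ed); no centring is applied
#' here.
#'
#' @param mc a `MuContainer`, or a plain named list of matrices sharing
#'   rows.
#' @param n_factors number of factors.
#' @param balance divide each modality block by its top singular value so
#'   no modality dominates by scale?
#' @param layer optional layer name to factorise instead of `X`.
#' @return A `JointFactorModel`: `Z` (`n x K`), `W` (named list of
#'   feature x K blocks), `r2` (`M x K` matrix), `singular_values`.
#' @export
joint_factor_svd <- function(mc, n_factors, balance = FALSE, layer = NULL) {
  if (inherits(mc, "MuContainer")) {
    stop_if_stale(mc)
    shared <- vapply(mc$obsmap, function(m) all(m > 0L), TRUE)
    if (!all(shared))
      stop("all modalities must share all observations; run intersect_obs() first")
    blocks <- lapply(mc$mod, function(am) {
      m <- if (is.null(layer)) am$X else am$layers[[layer]]
      as.matrix(materialize(m))
    })
  } else blocks <- lapply(mc, as.matrix)
  M <- length(blocks)
  n <- nrow(blocks[[1L]])
  if (balance)
    blocks <- lapply(blocks, function(B) {
      top <- svd(B, nu = 0, nv = 0)$d[1L]
      if (top > 0) B / top else B
    })
  Xc <- do.call(cbind, blocks)
  if (n_factors >= min(dim(Xc)))
    stop(sprintf("n_factors = %d must be < min(n, total d) = %d", n_factors, min(dim(Xc))))
  sv <- svd(Xc, nu = n_factors, nv = n_factors)
  d <- sv$d[seq_len(n_factors)]
  u <- sv$u; v <- sv$v
  for (k in seq_len(n_factors)) {
    piv <- which.max(abs(v[, k]))
    if (v[piv, k] < 0) { v[, k] <- -v[, k]; u[, k] <- -u[, k] }
  }
  offsets <- cumsum(c(0L, vapply(blocks, ncol, 0L)))
  W <- stats::setNames(lapply(seq_len(M), function(m)
    v[(offsets[m] + 1L):offsets[m + 1L], , drop = FALSE]), names(blocks))
  r2 <- matrix(0, M, n_factors, dimnames = list(names(blocks), NULL))
  for (m in seq_len(M)) {
    denom <- sum(blocks[[m]]^2)
    if (denom > 0)
      r2[m, ] <- d^2 * colSums(W[[m]]^2) / denom
  }
  structure(list(Z = u %*% diag(d, n_factors), W = W, r2 = r2, singular_values = d),
            class = "JointFactorModel")
}

#' Hand a neighbour graph to an external nonlinear embedder
#'
#' Adapter contract only: the package does not implement manifold
#' embedding. `embedder` receives the graph's connectivity matrix and
#' must return an `n x 2` (or wider) coordinate matrix, which is
#' returned (and, when a container is supplied, stored under
#' `obsm[["X_umap"]]`).
#'
#' @param graph a `NeighborGraph`.
#' @param embedder function taking a sparse connectivity matrix and
#'   returning a coordinate matrix; if `NULL` a capability error of
#'   class `mudkit_capability_error` is raised.
#' @param mc optional `MuContainer` in which to store the coordinates.
#' @return The coordinates, or the container with `obsm[["X_umap"]]` set.
#' @export
fused_umap <- function(graph, embedder = NULL, mc = NULL) {
  if (!inherits(graph, "NeighborGraph")) stop("graph must be a NeighborGraph")
  n <- nrow(graph$connectivities)
  if (n == 0L) stop("graph has no observations")
  if (is.null(embedder))
    stop(errorCondition(
      "no external embedder supplied: nonlinear embedding (e.g. UMAP) is consumed via this adapter, not implemented",
      class = c("mudkit_capability_error", "error")))
  coords <- embedder(graph$connectivities)
  coords <- as.matrix(coords)
  if (nrow(coords) != n)
    stop(sprintf("embedder returned %d rows for %d observations", nrow(coords), n))
  if (is.null(mc)) return(coords)
  mc$obsm[["X_umap"]] <- coords
  mc
}
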