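#' Library-size normalisation with log transform
#'
#' Scales every observation (row) to a common total `scale_factor`, then
#' applies `log1p`. Rows with zero total are left all-zero. Zero entries
#' stay exactly zero, so sparsity patterns are preserved.
#'
#' @param X non-negative counts matrix (dense or sparse), observations in
#'   rows.
#' @param scale_factor target row total before the log (default `1e4`,
#'   the convention for single-cell counts).
#' @return Matrix of the same storage class as `X`.
#' @examples
#' normalize_total_log1p(matrix(c(2, 2), 1))  # both entries log1p(5000)
#' @export
normalize_total_log1p <- function(X, scale_factor = 1e4) {
  check_nonneg(X)
  rs <- Matrix::rowSums(X)
  sf <- ifelse(rs > 0, scale_factor / rs, 0)
  if (inherits(X, "sparseMatrix")) {
    out <- Matrix::Diagonal(x = sf) %*% X
    out <- methods::as(methods::as(out, "generalMatrix"),
                       if (inherits(X, "RsparseMatrix")) "RsparseMatrix" else "CsparseMatrix")
    out@x <- log1p(out@x)
    dimnames(out) <- dimnames(X)
    out
  } else {
    log1p(X * sf)
  }
}

#' Centre and scale features, with clipping
#'
#' Each column is centred to mean zero and scaled to unit *population*
#' standard deviation (zero-variance columns become all-zero), then
#' values are clipped to `[-max_value, max_value]`. Output is dense.
#'
#' @param X finite numeric matrix, observations in rows.
#' @param max_value clip bound after scaling (default 10).
#' @return Dense numeric matrix.
#' @export
scale_center <- function(X, max_value = 10) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite")
  n <- nrow(X)
  mu <- colMeans(X)
  sd_pop <- sqrt(colMeans(X^2) - mu^2)
  sd_pop[sd_pop <= 0 | !is.finite(sd_pop)] <- Inf   # constant column -> zeros
  out <- sweep(sweep(X, 2L, mu, "-"), 2L, sd_pop, "/")
  out[out > max_value] <- max_value
  out[out < -max_value] <- -max_value
  out
}

#' Select highly variable features by binned normalised dispersion
#'
#' For each feature the dispersion `var/mean` is computed on the
#' log-normalised matrix; features are cut into 20 equal-count bins of
#' mean expression and dispersions are z-scored within each bin; the
#' `n_top` features with the largest z-scores are selected, breaking ties
#' deterministically toward the lower feature index.
#'
#' @param X_lognorm log-normalised matrix, observations in rows.
#' @param n_top number of features to select (`1 <= n_top <= n_var`).
#' @param n_bins number of mean-expression bins.
#' @return Logical mask of length `ncol(X_lognorm)`.
#' @export
select_hvf <- function(X_lognorm, n_top, n_bins = 20L) {
  d <- ncol(X_lognorm)
  if (!is.numeric(n_top) || n_top <= 0) stop("n_top must be positive")
  if (n_top > d) stop(sprintf("n_top = %d exceeds the number of features (%d)", n_top, d))
  X <- as.matrix(X_lognorm)
  mu <- colMeans(X)
  v <- colMeans(X^2) - mu^2
  disp <- ifelse(mu > 0, v / mu, 0)
  # equal-count bins on the mean; duplicated quantiles collapse bins
  qs <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1L)))
  bins <- if (length(qs) > 2L) cut(mu, breaks = qs, include.lowest = TRUE)
  else factor(rep(1L, d))
  z <- numeric(d)
  g_m <- mean(disp); g_s <- stats::sd(disp)
  for (b in levels(bins)) {
    i <- which(bins == b)
    m <- mean(disp[i]); s <- stats::sd(disp[i])
    # degenerate bins (singletons, ties) fall back to the global scale so
    # an isolated high-dispersion feature is not silenced
    z[i] <- if (length(i) > 1L && isTRUE(s > 0)) (disp[i] - m) / s
    else if (isTRUE(g_s > 0)) (disp[i] - g_m) / g_s
    else 0
  }
  sel <- order(-z, seq_len(d))[seq_len(n_top)]
  seq_len(d) %in% sel
}

#' Term frequency - inverse document frequency transform
#'
#' The standard reweighting for cells x peaks accessibility matrices:
#' `TF[i,j] = x[i,j] / rowsum(i)` (zero rows stay zero),
#' `IDF[j] = n_obs / df[j]` with `df[j]` the number of cells in which
#' feature `j` is detected (features detected nowhere get IDF 0), and the
#' result is `log1p(TF * IDF * scale_factor)`. Zero entries remain zero.
#'
#' @param X non-negative matrix, observations in rows.
#' @param scale_factor multiplier inside the log (default `1e4`).
#' @return Matrix of the same storage class as `X`.
#' @export
tfidf <- function(X, scale_factor = 1e4) {
  check_nonneg(X)
  n <- nrow(X)
  rs <- Matrix::rowSums(X)
  inv_rs <- ifelse(rs > 0, 1 / rs, 0)
  df <- Matrix::colSums(X > 0)
  idf <- ifelse(df > 0, n / df, 0)
  if (inherits(X, "sparseMatrix")) {
    out <- Matrix::Diagonal(x = inv_rs) %*% X %*% Matrix::Diagonal(x = idf)
    out <- methods::as(methods::as(out, "generalMatrix"),
                       if (inherits(X, "RsparseMatrix")) "RsparseMatrix" else "CsparseMatrix")
    out@x <- log1p(out@x * scale_factor)
    dimnames(out) <- dimnames(X)
    out
  } else {
    log1p((X * inv_rs) %*% diag(idf, ncol(X)) * scale_factor)
  }
}

check_nonneg <- function(X) {
  mn <- if (inherits(X, "sparseMatrix")) min(0, X@x) else min(X)
  if (mn < 0) stop("matrix must be non-negative")
  invisible(X)
}

#' Latent semantic indexing of a TF-IDF matrix
#'
#' Truncated singular value decomposition of the (uncentred) TF-IDF
#' matrix. Components use a deterministic sign convention (the
#' largest-magnitude loading of each component is positive). The first
#' component of an LSI decomposition typically tracks sequencing depth;
#' `drop_first = TRUE` removes it and returns `n_comps - 1` columns.
#'
#' @param X_tfidf matrix, observations in rows (sparse accepted;
#'   densified for the decomposition — this is a desk-scale reduction).
#' @param n_comps number of components (`< min(n_obs, n_var)`).
#' @param drop_first drop the depth-correlated first component?
#' @return A list of class `LsiResult`: `components` (cell embedding,
#'   `n x K`), `singular_values` (non-increasing), `loadings`
#'   (feature x K, unit-norm columns).
#' @export
lsi <- function(X_tfidf, n_comps, drop_first = FALSE) {
  X <- as.matrix(X_tfidf)
  if (n_comps >= min(dim(X)))
    stop(sprintf("n_comps = %d must be < min(n_obs, n_var) = %d", n_comps, min(dim(X))))
  sv <- svd(X, nu = n_comps, nv = n_comps)
  d <- sv$d[seq_len(n_comps)]
  u <- sv$u; v <- sv$v
  for (k in seq_len(n_comps)) {           # sign: largest-|loading| positive
    piv <- which.max(abs(v[, k]))
    if (v[piv, k] < 0) { v[, k] <- -v[, k]; u[, k] <- -u[, k] }
  }
  keep <- if (drop_first) seq_len(n_comps)[-1L] else seq_len(n_comps)
  structure(list(components = u[, keep, drop = FALSE] %*% diag(d[keep], length(keep)),
                 singular_values = d[keep],
                 loadings = v[, keep, drop = FALSE]),
            class = "LsiResult")
}

#' Background-based denoising and scaling of epitope counts
#'
#' Normalises antibody-derived-tag (surface protein) counts against the
#' ambient background measured in empty droplets, then removes a per-cell
#' technical factor:
#'
#' 1. both matrices are `log1p`-transformed;
#' 2. each protein is z-scored in the cells using the empty-droplet mean
#'    and population standard deviation (sd floored at `1e-3`);
#' 3. for every cell a univariate two-component Gaussian mixture is fit
#'    to its protein z-score vector by EM with a deterministic
#'    initialisation (component means at the 25th/75th percentiles,
#'    equal weights, pooled variance; at most 500 iterations or a
#'    log-likelihood change below `1e-8`); the technical factor
#'    `lambda[i]` is the fitted mean of the lower component;
#' 4. the output is `z[i,j] - lambda[i]`.
#'
#' @param X_cells cells x proteins count matrix.
#' @param X_empty empty-droplets x proteins count matrix over the same
#'   proteins (at least 20 droplets).
#' @return A list with `mat` (denoised matrix) and `fit`, a `DsbFit` with
#'   `mu_bg`/`sigma_bg` (per-protein background statistics on the log1p
#'   scale) and `lambda` (per-cell technical factor).
#' @export
dsb_normalize <- function(X_cells, X_empty) {
  X_cells <- as.matrix(X_cells); X_empty <- as.matrix(X_empty)
  if (ncol(X_cells) != ncol(X_empty))
    stop("cell and empty-droplet matrices must share the same proteins")
  if (ncol(X_cells) < 2L) stop("at least 2 proteins are required for the per-cell mixture")
  if (nrow(X_empty) < 20L) stop("at least 20 empty droplets are required")
  if (!all(is.finite(X_cells)) || !all(is.finite(X_empty))) stop("non-finite input")

  lc <- log1p(X_cells); le <- log1p(X_empty)
  mu_bg <- colMeans(le)
  sigma_bg <- pmax(sqrt(colMeans(le^2) - mu_bg^2), 1e-3)
  z <- sweep(sweep(lc, 2L, mu_bg, "-"), 2L, sigma_bg, "/")
  lambda <- apply(z, 1L, gmm2_lower_mean)
  structure(
    list(mat = z - lambda,
         fit = structure(list(mu_bg = mu_bg, sigma_bg = sigma_bg, lambda = lambda),
                         class = "DsbFit")),
    class = "DsbResult")
}

# Technical factor of one cell: EM for a univariate 2-component Gaussian
# mixture, guarded by an ICL comparison against the single-Gaussian fit.
# Initialisation is deterministic: the optimal 1-D two-cluster partition
# (threshold scan minimising within-cluster sum of squares) supplies the
# starting means and weights, so a small positive-protein component is
# found even when it holds few proteins. The guard matters: on a unimodal
# z-vector (a cell with no positive proteins) an unconditional
# 2-component fit straddles the bulk and the "lower component mean" is a
# severely biased location estimate; ICL (BIC plus the assignment-entropy
# penalty, the mclust model-selection criterion) rejects such overlapping
# splits and falls back to the plain mean, while clearly bimodal
# marker-positive cells keep the mixture estimate. The variance floor
# (0.01 on the z-scale) blocks degenerate spike components.
gmm2_lower_mean <- function(x, max_iter = 500L, tol = 1e-8, var_floor = 1e-2) {
  n <- length(x)
  m0 <- mean(x); s0 <- sqrt(max(mean((x - m0)^2), var_floor))
  icl1 <- -2 * sum(stats::dnorm(x, m0, s0, log = TRUE)) + 2 * log(n)
  xs <- sort(x)
  if (xs[n] - xs[1] < 1e-12) return(m0)     # (near-)constant vector
  cs1 <- cumsum(xs); cs2 <- cumsum(xs^2)
  k <- seq_len(n - 1L)
  ssw <- (cs2[k] - cs1[k]^2 / k) +
    ((cs2[n] - cs2[k]) - (cs1[n] - cs1[k])^2 / (n - k))
  kb <- which.min(ssw)
  mu <- c(cs1[kb] / kb, (cs1[n] - cs1[kb]) / (n - kb))
  s2 <- rep(max(stats::var(x), var_floor), 2L)  # pooled variance init
  w <- c(kb, n - kb) / n
  ll_old <- -Inf; ll <- -Inf; r <- rep(0.5, n)
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sqrt(s2[1]))
    d2 <- w[2] * stats::dnorm(x, mu[2], sqrt(s2[2]))
    tot <- pmax(d1 + d2, .Machine$double.xmin)
    r <- d1 / tot
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
    n1 <- sum(r); n2 <- n - n1
    if (n1 < 1e-10 || n2 < 1e-10) break
    mu <- c(sum(r * x) / n1, sum((1 - r) * x) / n2)
    s2 <- pmax(c(sum(r * (x - mu[1])^2) / n1,
                 sum((1 - r) * (x - mu[2])^2) / n2), var_floor)
    w <- c(n1, n2) / n
  }
  rc <- pmin(pmax(r, 1e-12), 1 - 1e-12)
  ent <- -sum(rc * log(rc) + (1 - rc) * log(1 - rc))
  icl2 <- -2 * ll + 5 * log(n) + 2 * ent
  if (icl2 >= icl1) return(m0)
  # the background is by assumption the majority of the panel: a minority
  # lower component is a left-tail artifact of discrete counts, in which
  # case the dominant component carries the cell's technical location
  lo <- which.min(mu)
  if (w[lo] >= 0.5) mu[lo] else mu[3L - lo]
}
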