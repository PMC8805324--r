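# ---- PCA -----------------------------------------------------------------

test_that("collinear points put all variance on the first component", {
  t <- seq(-2, 2, length.out = 10)
  X <- cbind(3 * t + 1, -2 * t + 5)
  p <- pca(X, 1)
  expect_equal(p$explained_variance_ratio[1], 1, tolerance = 1e-9)
})

test_that("PCA agrees with a dense eigensolver oracle", {
  for (seed in 1:10) {
    X <- withr::with_seed(seed, matrix(rnorm(240), 30, 8))
    p <- pca(X, 4)
    Xc <- sweep(X, 2, colMeans(X), "-")
    eig <- eigen(crossprod(Xc), symmetric = TRUE)      # independent route
    oracle <- Xc %*% eig$vectors[, 1:4]
    expect_equal(abs(unname(p$coords)), abs(oracle), tolerance = 1e-8)
    expect_lte(sum(p$explained_variance_ratio), 1 + 1e-12)
    expect_false(is.unsorted(rev(p$explained_variance_ratio)))
    expect_equal(p$explained_variance_ratio,
                 eig$values[1:4] / sum(eig$values), tolerance = 1e-8)
  }
})

# ---- kNN -----------------------------------------------------------------

test_that("collinear points pick the expected neighbours", {
  g <- knn(matrix(c(0, 1, 3), 3, 1), k = 1)
  expect_identical(g$indices[, 1], c(2L, 1L, 2L))
})

test_that("each cell's nearest neighbour has connectivity one", {
  X <- withr::with_seed(3, matrix(rnorm(60), 20, 3))
  g <- knn(X, 5)
  first <- vapply(1:20, function(i) g$connectivities[i, g$indices[i, 1]], 0)
  expect_equal(first, rep(1, 20), tolerance = 1e-12)
  expect_true(all(g$connectivities@x > 0 & g$connectivities@x <= 1))
  expect_false(any(vapply(1:20, function(i) i %in% g$indices[i, ], TRUE)))
  expect_false(any(apply(g$distances, 1, is.unsorted)))
})

test_that("the graph equals the brute-force oracle on random point sets", {
  for (seed in 1:50) {
    withr::with_seed(seed, {
      n <- sample(8:20, 1); d <- sample(1:4, 1); k <- sample(2:5, 1)
      X <- matrix(rnorm(n * d), n, d)
      if (seed %% 7 == 0) X[2, ] <- X[1, ]          # duplicated points
      g <- knn(X, k)
      o <- oracle_knn(X, k)
      expect_identical(g$indices, o$indices)
      expect_equal(g$distances, o$distances, tolerance = 1e-12)
      expect_equal(as.matrix(g$connectivities), o$connectivities,
                   tolerance = 1e-12, ignore_attr = TRUE)
    })
  }
})

test_that("k must leave room for a neighbour set", {
  expect_error(knn(matrix(rnorm(10), 5, 2), 5), "k = 5")
})

# ---- WNN -----------------------------------------------------------------

# literal loop-based transcription of the weighting formulas
oracle_wnn_weights <- function(embeddings, k, eps = 1e-4) {
  M <- length(embeddings); n <- nrow(embeddings[[1]])
  nn <- list(); d1 <- matrix(0, n, M); sg <- matrix(0, n, M)
  for (m in 1:M) {
    E <- embeddings[[m]]
    idx <- matrix(0L, n, k)
    for (i in 1:n) {
      dd <- sqrt(colSums((t(E) - E[i, ])^2))
      ord <- setdiff(order(dd, seq_len(n)), i)[1:k]
      idx[i, ] <- ord
      d1[i, m] <- dd[ord[1]]; sg[i, m] <- dd[ord[k]]
    }
    nn[[m]] <- idx
  }
  s <- matrix(0, n, M)
  for (m in 1:M) for (i in 1:n) {
    E <- embeddings[[m]]
    th <- numeric(M)
    for (m2 in 1:M) {
      pred <- colMeans(E[nn[[m2]][i, ], , drop = FALSE])
      derr <- sqrt(sum((E[i, ] - pred)^2))
      th[m2] <- exp(-max(derr - d1[i, m], 0) / max(sg[i, m] - d1[i, m], eps))
    }
    s[i, m] <- th[m] / (mean(th[-m]) + eps)
  }
  w <- matrix(0, n, M)
  for (i in 1:n) w[i, ] <- exp(s[i, ] - max(s[i, ])) / sum(exp(s[i, ] - max(s[i, ])))
  w
}

test_that("weights match a literal formula transcription for M = 2 and M = 3", {
  for (M in 2:3) {
    embeddings <- withr::with_seed(40 + M,
      lapply(seq_len(M), function(m) matrix(rnorm(30 * 3), 30, 3)))
    res <- wnn(embeddings, k = 5, k_out = 5)
    expect_equal(res$weights, oracle_wnn_weights(embeddings, k = 5),
                 tolerance = 1e-10)
  }
})

test_that("weight rows live on the simplex and respect symmetries", {
  E <- withr::with_seed(1, matrix(rnorm(40 * 2), 40, 2))
  F1 <- withr::with_seed(2, matrix(rnorm(40 * 2), 40, 2))
  res <- wnn(list(E, F1), k = 6)
  expect_equal(rowSums(res$weights), rep(1, 40), tolerance = 1e-9)
  expect_true(all(res$weights >= 0))
  # permuting modalities permutes the weight columns
  res2 <- wnn(list(F1, E), k = 6)
  expect_equal(res2$weights, res$weights[, 2:1], tolerance = 1e-12)
  # identical copies: exactly 1/M
  for (M in 2:3) {
    resM <- wnn(rep(list(E), M), k = 6)
    expect_identical(unique(as.vector(resM$weights)), 1 / M)
  }
})

test_that("an informative modality dominates an uninformative one", {
  withr::with_seed(42, {
    n <- 300
    centers <- matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE)
    A <- centers[rep(1:3, each = 100), ] + matrix(rnorm(n * 2), n, 2)
    B <- matrix(rnorm(n * 2), n, 2)
    res <- wnn(list(signal = A, noise = B), k = 20, k_out = 20)
    expect_gt(mean(res$weights[, 1]), 0.7)
  })
})

test_that("degenerate inputs are rejected", {
  E <- matrix(rnorm(20), 10, 2)
  expect_error(wnn(list(E)), "two modalities")
  expect_error(wnn(list(E, E[1:5, ])), "row counts differ")
  expect_error(wnn(list(E, matrix(1, 10, 2))), "zero variance")
  expect_error(wnn(list(E, E), k = 10), "k = 10")
})

# ---- joint factorisation -------------------------------------------------

test_that("a shared rank-1 factor is recovered in both modalities", {
  withr::with_seed(7, {
    z <- rnorm(100)
    X1 <- z %*% t(rnorm(30)) + matrix(rnorm(3000, 0, 0.05), 100, 30)
    X2 <- z %*% t(rnorm(40)) + matrix(rnorm(4000, 0, 0.05), 100, 40)
    fit <- joint_factor_svd(list(a = X1, b = X2), n_factors = 1)
    expect_gt(abs(cor(fit$Z[, 1], z)), 0.99)
    expect_gt(fit$r2["a", 1], 0.9)
    expect_gt(fit$r2["b", 1], 0.9)
  })
})

test_that("a modality-specific factor shows an asymmetric variance share", {
  withr::with_seed(8, {
    z <- rnorm(150)
    X1 <- z %*% t(rnorm(25)) + matrix(rnorm(150 * 25, 0, 0.3), 150, 25)
    X2 <- matrix(rnorm(150 * 25), 150, 25)                 # pure noise
    fit <- joint_factor_svd(list(a = X1, b = X2), n_factors = 1)
    expect_gt(fit$r2["a", 1] / fit$r2["b", 1], 5)
  })
})

test_that("factor columns are orthogonal and variance shares bounded", {
  mc <- simulate_multiome(sim_params(n_cells = 120L, seed = 4L))
  blocks <- list(rna = scale_center(normalize_total_log1p(mc$mod$rna$X)),
                 atac = scale_center(tfidf(mc$mod$atac$X)))
  fit <- joint_factor_svd(blocks, n_factors = 5)
  G <- crossprod(fit$Z)
  expect_equal(G - diag(diag(G)), matrix(0, 5, 5), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(fit$r2 >= 0 & fit$r2 <= 1))
  expect_true(all(rowSums(fit$r2) <= 1 + 1e-6))
})

test_that("a single unbalanced modality reduces to PCA on centred input", {
  X <- withr::with_seed(5, matrix(rnorm(200), 40, 5))
  Xc <- sweep(X, 2, colMeans(X), "-")
  fit <- joint_factor_svd(list(only = Xc), n_factors = 3, balance = FALSE)
  p <- pca(X, 3)
  expect_equal(abs(unname(fit$Z)), abs(unname(p$coords)), tolerance = 1e-8)
})

test_that("missing observations in a modality are refused with guidance", {
  mc <- toy_container()
  expect_error(joint_factor_svd(mc, 1), "intersect_obs")
  shared <- intersect_obs(mc)
  expect_silent(fit <- joint_factor_svd(shared, 1))
  expect_identical(nrow(fit$Z), 2L)
})

# ---- embedding adapter ---------------------------------------------------

test_that("the embedding adapter enforces its contract", {
  g <- knn(matrix(rnorm(30), 15, 2), 4)
  expect_s3_class(tryCatch(fused_umap(g), error = identity),
                  "mudkit_capability_error")
  mock <- function(conn) cbind(seq_len(nrow(conn)), 0)
  coords <- fused_umap(g, embedder = mock)
  expect_identical(dim(coords), c(15L, 2L))
  expect_error(fused_umap(g, embedder = function(conn) matrix(0, 3, 2)), "15")
  # stored coordinates survive serialisation
  mc <- make_container(list(m = toy_mod(sprintf("c%02d", 1:15), c("g1", "g2"))))
  mc <- fused_umap(g, embedder = mock, mc = mc)
  f <- tmp_h5mu()
  write_h5mu(mc, f)
  expect_equal(read_h5mu(f)$obsm$X_umap, coords, ignore_attr = TRUE)
})
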