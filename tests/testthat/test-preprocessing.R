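test_that("library-size log-normalisation matches hand computation", {
  out <- normalize_total_log1p(matrix(c(2, 2), 1, 2))
  expect_equal(unname(out), matrix(log1p(5000), 1, 2), tolerance = 1e-12)
  X <- rbind(c(2, 2), c(0, 0), c(1, 3))
  out <- normalize_total_log1p(X)
  expect_identical(unname(out[2, ]), c(0, 0))                 # zero row stays zero
  expect_equal(sum(expm1(out[1, ])), 1e4, tolerance = 1e-8)   # conservation
  expect_equal(sum(expm1(out[3, ])), 1e4, tolerance = 1e-8)
  expect_error(normalize_total_log1p(matrix(c(-1, 2), 1)), "non-negative")
})

test_that("normalisation preserves the sparsity pattern", {
  X <- as_csr(matrix(c(0, 3, 0, 5, 0, 2), 2, 3))
  out <- normalize_total_log1p(X)
  expect_s4_class(out, "RsparseMatrix")
  expect_identical(as.matrix(out == 0), as.matrix(X == 0))
  ti <- tfidf(X)
  expect_identical(as.matrix(ti == 0), as.matrix(X == 0))
})

test_that("scale_center centres to zero mean, unit population sd, and clips", {
  out <- scale_center(matrix(c(1, 3), 2, 1))
  expect_equal(unname(out), matrix(c(-1, 1), 2, 1), tolerance = 1e-12)
  expect_identical(unname(scale_center(matrix(5, 4, 1))), matrix(0, 4, 1))
  big <- scale_center(matrix(c(rep(0, 99), 1000), 100, 1), max_value = 10)
  expect_lte(max(abs(big)), 10)
  # idempotent up to clipping
  X <- matrix(rnorm(60), 20, 3)
  once <- scale_center(X)
  expect_equal(scale_center(once), once, tolerance = 1e-12)
})

test_that("highly variable feature selection is deterministic and finds planted signal", {
  X <- matrix(rpois(200, 5), 20, 10)
  expect_identical(select_hvf(normalize_total_log1p(X), 10), rep(TRUE, 10))
  expect_error(select_hvf(X, 0), "positive")
  expect_error(select_hvf(X, 11), "exceeds")
  # identical columns tie toward the lower index
  Xt <- cbind(X[, 1], X[, 1], X[, 2:3])
  mask <- select_hvf(Xt, 1)
  expect_true(mask[1] || !mask[2])
  # planted high-variance feature always wins at n_top = 1
  hits <- vapply(1:20, function(s) withr::with_seed(s, {
    n <- 100
    Xs <- matrix(rpois(n * 15, 10), n, 15)
    Xs[, 7] <- rpois(n, 10) * sample(c(1L, 10L), n, replace = TRUE)
    which(select_hvf(normalize_total_log1p(Xs), 1))
  }), 1L)
  expect_true(all(hits == 7L))
})

test_that("TF-IDF matches the hand-computed 2x2 example and is depth-free", {
  X <- rbind(c(1, 1), c(0, 1))
  out <- tfidf(X)
  want <- rbind(c(log1p(1e4), log1p(5e3)), c(0, log1p(1e4)))
  expect_equal(unname(out), want, tolerance = 1e-12)
  # equal term frequencies for an always-present feature give equal outputs
  Xe <- rbind(c(3, 1), c(6, 2))
  oe <- tfidf(Xe)
  expect_equal(oe[1, 1], oe[2, 1], tolerance = 1e-12)
  # doubling a cell's counts leaves its row unchanged
  Xd <- matrix(rpois(50, 3), 5, 10)
  o1 <- tfidf(Xd)
  Xd2 <- Xd; Xd2[3, ] <- Xd[3, ] * 2
  expect_equal(tfidf(Xd2)[3, ], o1[3, ], tolerance = 1e-12)
})

test_that("LSI is an exact truncated SVD with ordered spectrum", {
  set.seed(1)
  A <- matrix(rnorm(40), 20, 2) %*% matrix(rnorm(16), 2, 8)   # exact rank 2
  r <- lsi(A, 2)
  rec <- r$components %*% t(r$loadings)
  expect_lt(norm(A - rec, "F"), 1e-8)
  expect_false(is.unsorted(rev(r$singular_values)))
  expect_equal(colSums(r$loadings^2), rep(1, 2), tolerance = 1e-10)
  expect_error(lsi(A, 10), "n_comps")
  r2 <- lsi(A, 2, drop_first = TRUE)
  expect_identical(ncol(r2$components), 1L)
})

test_that("the first LSI component tracks sequencing depth", {
  mc <- simulate_multiome(sim_params(n_cells = 200L, seed = 3L))
  r <- lsi(tfidf(mc$mod$atac$X), 10)
  depth <- log(Matrix::rowSums(mc$mod$atac$X))
  expect_gt(abs(cor(r$components[, 1], depth)), 0.9)
})
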