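# Fixtures are generated in code; nothing is stored on disk.

as_csr <- function(m) {
  methods::as(methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                      "dMatrix"), "generalMatrix"), "RsparseMatrix")
}

toy_mod <- function(cells, features, sparse = FALSE, seed = 1L) {
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(length(cells) * length(features), 4),
                length(cells), length(features),
                dimnames = list(cells, features))
    AnnotatedMatrix(if (sparse) as_csr(m) else m)
  })
}

# the two-modality example container: rna over c1..c3, atac over c2..c4
toy_container <- function() {
  make_container(list(
    rna = toy_mod(c("c1", "c2", "c3"), c("g1", "g2"), seed = 1L),
    atac = toy_mod(c("c2", "c3", "c4"), c("p1", "p2"), sparse = TRUE, seed = 2L)))
}

# seeded random container mixing dense/CSR matrices, numeric / integer /
# boolean / categorical columns with missing values, 1-3 modalities,
# cells missing per modality, shared feature names, layers, embeddings,
# pairwise slots and nested uns.
random_container <- function(seed) {
  withr::with_seed(seed, {
    n_mod <- sample(1:3, 1)
    pool <- sprintf("c%02d", 1:12)
    shared_feature <- "featX"
    mods <- list()
    for (i in seq_len(n_mod)) {
      n <- sample(4:10, 1)
      cells <- sort(sample(pool, n))
      d <- sample(3:7, 1)
      feats <- c(sprintf("m%d_f%d", i, seq_len(d - 1)), shared_feature)
      m <- matrix(stats::rpois(n * d, 5), n, d, dimnames = list(cells, feats))
      X <- if (stats::runif(1) < 0.5) as_csr(m) else m
      obs <- data.frame(row.names = cells)
      obs$score <- stats::rnorm(n)
      obs$score[sample(n, 1)] <- NA
      obs$count <- sample(c(NA_integer_, 1:50), n, replace = TRUE)
      obs$flag <- sample(c(TRUE, FALSE, NA), n, replace = TRUE)
      obs$type <- factor(sample(c("a", "b"), n, replace = TRUE),
                         levels = c("a", "b", "unused"))
      var <- data.frame(row.names = feats)
      var$gc <- stats::runif(d)
      layers <- list()
      if (stats::runif(1) < 0.5)
        layers$norm <- matrix(stats::rnorm(n * d), n, d)
      obsm <- if (stats::runif(1) < 0.5) list(X_pca = matrix(stats::rnorm(n * 2), n, 2)) else list()
      obsp <- if (stats::runif(1) < 0.3) list(conn = as_csr(matrix(stats::rbinom(n * n, 1, 0.2), n, n))) else list()
      mods[[paste0("mod", i)]] <- AnnotatedMatrix(m, obs = obs, var = var,
                                                  layers = layers, obsm = obsm, obsp = obsp,
                                                  uns = list(note = paste0("modality ", i)))
      mods[[paste0("mod", i)]]$X <- X
      dimnames(mods[[paste0("mod", i)]]$X) <- list(cells, feats)
    }
    mc <- make_container(mods)
    mc$obs$batch <- factor(sample(c("b1", "b2"), nrow(mc$obs), replace = TRUE))
    mc$uns <- list(title = "random fixture",
                   params = list(seed = as.integer(seed), alpha = 0.5),
                   weights = stats::rnorm(3))
    mc$obsm$X_joint <- matrix(stats::rnorm(nrow(mc$obs) * 2), nrow(mc$obs), 2)
    mu_update(mc)
  })
}

tmp_h5mu <- function() {
  f <- tempfile(fileext = ".h5mu")
  withr::defer_parent(unlink(f))
  f
}

# recursively sort named lists by key (JSON objects are unordered)
canon <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x)) && length(x)) x <- x[order(names(x))]
    lapply(x, canon)
  } else x
}

expect_container_equal <- function(a, b) {
  r <- container_equal(a, b)
  expect_true(isTRUE(r), info = if (!isTRUE(r)) r else NULL)
}

# independent per-slot subsetting oracle: slices every slot of every
# modality and the global slots directly, without using subset()
oracle_subset_obs <- function(mc, sel_names) {
  out <- mc
  osel <- match(sel_names, rownames(mc$obs))
  for (m in names(mc$mod)) {
    am <- mc$mod[[m]]
    keep_local <- match(sel_names, rownames(am$obs))
    keep_local <- keep_local[!is.na(keep_local)]
    am$X <- am$X[keep_local, , drop = FALSE]
    am$obs <- am$obs[keep_local, , drop = FALSE]
    am$layers <- lapply(am$layers, function(x) x[keep_local, , drop = FALSE])
    am$obsm <- lapply(am$obsm, function(x) x[keep_local, , drop = FALSE])
    am$obsp <- lapply(am$obsp, function(x) x[keep_local, keep_local, drop = FALSE])
    out$mod[[m]] <- am
    present <- sel_names %in% rownames(mc$mod[[m]]$obs)
    map <- integer(length(sel_names))
    map[present] <- seq_len(sum(present))
    out$obsmap[[m]] <- map
  }
  out$obs <- mc$obs[osel, , drop = FALSE]
  out$obsm <- lapply(mc$obsm, function(x) x[osel, , drop = FALSE])
  out$obsp <- lapply(mc$obsp, function(x) x[osel, osel, drop = FALSE])
  out
}

# AxisMap contract: nonzero entries are an increasing enumeration of the
# local axis, and names line up through the map
expect_axis_maps_valid <- function(mc) {
  for (m in names(mc$mod)) {
    map <- mc$obsmap[[m]]
    nz <- map[map > 0L]
    expect_identical(sort(nz), seq_len(nrow(mc$mod[[m]]$obs)))
    expect_false(is.unsorted(nz, strictly = TRUE))
    expect_identical(rownames(mc$obs)[map > 0L], rownames(mc$mod[[m]]$obs))
    vmap <- mc$varmap[[m]]
    nzv <- vmap[vmap > 0L]
    expect_identical(sort(nzv), seq_len(nrow(mc$mod[[m]]$var)))
    expect_false(is.unsorted(nzv, strictly = TRUE))
  }
}

# greedy |correlation| matching of estimated to true factors
greedy_match <- function(cm) {
  K <- ncol(cm); out <- numeric(K)
  for (k in seq_len(K)) {
    best <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    out[best[2]] <- cm[best[1], best[2]]
    cm[best[1], ] <- -1; cm[, best[2]] <- -1
  }
  out
}


# independent O(n^2) transcription of the neighbour and kernel rules
oracle_knn <- function(coords, k, eps = 1e-6) {
  n <- nrow(coords)
  D <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) D[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
  idx <- matrix(0L, n, k); dst <- matrix(0, n, k)
  for (i in 1:n) {
    cand <- setdiff(order(D[i, ], seq_len(n)), i)[1:k]
    idx[i, ] <- cand; dst[i, ] <- D[i, cand]
  }
  C <- matrix(0, n, n)
  for (i in 1:n) for (jj in 1:k) {
    j <- idx[i, jj]
    C[i, j] <- exp(-max(dst[i, jj] - dst[i, 1], 0) / max(dst[i, k] - dst[i, 1], eps))
  }
  for (i in 1:n) for (j in 1:n) C[i, j] <- max(C[i, j], C[j, i])
  list(indices = idx, distances = dst, connectivities = C)
}

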