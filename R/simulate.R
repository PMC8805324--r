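#' Parameters for the synthetic multimodal generators
#'
#' Bundles the sizes and noise levels shared by [simulate_multiome()] and
#' [simulate_citeseq()]. The generators are pure functions of these
#' parameters: equal seeds give byte-identical containers.
#'
#' @param n_cells number of cells.
#' @param n_groups number of discrete cell populations.
#' @param k_factors number of latent factors driving the modalities.
#' @param n_genes,n_peaks,n_proteins feature panel sizes.
#' @param depth_lognormal_sigma log-normal sd of per-cell size factors
#'   (sequencing-depth dispersion).
#' @param noise_sd residual noise sd added to the linear predictors.
#' @param n_empty number of empty droplets (CITE-seq preset).
#' @param seed integer seed; fully determines the output.
#' @return A list of class `SimParams`.
#' @export
sim_params <- function(n_cells = 300L, n_groups = 3L, k_factors = 4L,
                       n_genes = 200L, n_peaks = 300L, n_proteins = 30L,
                       depth_lognormal_sigma = 0.3, noise_sd = 0.2,
                       n_empty = 5000L, seed = 1L) {
  p <- list(n_cells = as.integer(n_cells), n_groups = as.integer(n_groups),
            k_factors = as.integer(k_factors), n_genes = as.integer(n_genes),
            n_peaks = as.integer(n_peaks), n_proteins = as.integer(n_proteins),
            depth_lognormal_sigma = depth_lognormal_sigma, noise_sd = noise_sd,
            n_empty = as.integer(n_empty), seed = as.integer(seed))
  counts <- c("n_cells", "n_groups", "k_factors", "n_genes", "n_peaks",
              "n_proteins", "n_empty")
  for (nm in counts) if (p[[nm]] < 1L) stop(sprintf("%s must be >= 1", nm))
  if (p$depth_lognormal_sigma < 0 || p$noise_sd < 0) stop("dispersions must be >= 0")
  structure(p, class = "SimParams")
}

# latent factor matrix: discrete group contrasts (continuous programs for
# factors beyond the group count), whitened so factor columns are exactly
# uncorrelated with unit sd, then given strictly decreasing strengths --
# the standard factor-analysis identifiability assumptions.
sim_latent <- function(n_cells, n_groups, K) {
  groups <- factor(paste0("g", sample.int(n_groups, n_cells, replace = TRUE)),
                   levels = paste0("g", seq_len(n_groups)))
  A <- matrix(stats::rnorm(n_groups * K, sd = 2), n_groups, K)
  F0 <- A[as.integer(groups), , drop = FALSE] + matrix(stats::rnorm(n_cells * K), n_cells, K)
  F0 <- sweep(F0, 2L, colMeans(F0), "-")
  Fw <- F0 %*% backsolve(chol(stats::cov(F0)), diag(K))
  strengths <- seq(2.5, 1, length.out = K)
  list(Z = Fw %*% diag(strengths, K), groups = groups, strengths = strengths)
}

softplus <- function(x) log1p(exp(pmin(x, 30))) + pmax(x - 30, 0)

#' Simulate a paired RNA + ATAC (multiome) container
#'
#' Both modalities are driven by a shared latent factor matrix `Z`
#' (discrete cell groups plus noise, whitened and given strictly
#' decreasing factor strengths; see the methods vignette). RNA counts are
#' Poisson with rate `softplus(Z W_rna') * size_factor`; ATAC is binary
#' Bernoulli with probability `sigmoid(Z W_atac' + peak offsets)` and
#' stored row-sparse. The last factor loads only on RNA, providing a
#' modality-specific factor for variance-decomposition checks. Ground
#' truth (`Z`, loadings, group labels) is stored in `uns`/`obs`.
#'
#' @param params a [sim_params()] object.
#' @return A `MuContainer` with modalities `rna` and `atac` sharing all
#'   cells.
#' @export
simulate_multiome <- function(params = sim_params()) {
  stopifnot(inherits(params, "SimParams"))
  withr::with_seed(params$seed, {
    n <- params$n_cells; K <- params$k_factors
    lat <- sim_latent(n, params$n_groups, K)
    Z <- lat$Z
    cells <- sprintf("cell%04d", seq_len(n))

    W_rna <- matrix(stats::rnorm(params$n_genes * K, sd = 1 / sqrt(K)), params$n_genes, K)
    W_atac <- matrix(stats::rnorm(params$n_peaks * K, sd = 1.5 / sqrt(K)), params$n_peaks, K)
    if (K >= 2L) W_atac[, K] <- 0      # modality-specific factor (RNA only)

    sf <- exp(stats::rnorm(n, 0, params$depth_lognormal_sigma))
    eta_rna <- Z %*% t(W_rna) + matrix(stats::rnorm(n * params$n_genes, 0, params$noise_sd),
                                       n, params$n_genes)
    eta_rna <- sweep(eta_rna, 2L, stats::rnorm(params$n_genes, 0.5, 0.5), "+")
    rate <- softplus(eta_rna) * sf
    Xr <- matrix(stats::rpois(length(rate), rate), n, params$n_genes,
                 dimnames = list(cells, sprintf("gene%04d", seq_len(params$n_genes))))

    eta_atac <- Z %*% t(W_atac) + matrix(stats::rnorm(n * params$n_peaks, 0, params$noise_sd),
                                         n, params$n_peaks)
    eta_atac <- sweep(eta_atac, 2L, stats::rnorm(params$n_peaks, -1, 0.5), "+")
    p <- stats::plogis(eta_atac)
    Xa <- matrix(stats::rbinom(length(p), 1L, p), n, params$n_peaks,
                 dimnames = list(cells, sprintf("peak%04d", seq_len(params$n_peaks))))
    Xa <- methods::as(methods::as(methods::as(
      Matrix::Matrix(Xa, sparse = TRUE), "dMatrix"), "generalMatrix"), "RsparseMatrix")

    rna <- AnnotatedMatrix(Xr, obs = data.frame(group = lat$groups, row.names = cells))
    atac <- AnnotatedMatrix(Xa, obs = data.frame(group = lat$groups, row.names = cells))
    mc <- make_container(list(rna = rna, atac = atac))
    mc$uns$truth <- list(Z = Z, W_rna = W_rna, W_atac = W_atac,
                         strengths = lat$strengths, size_factors = sf)
    mc$obs$group <- lat$groups
    mc
  })
}

#' Simulate a CITE-seq container plus empty droplets
#'
#' Gene expression is generated as in [simulate_multiome()]. Protein
#' (antibody-derived tag) counts are negative binomial around an ambient
#' per-protein mean shared with the empty droplets; marker proteins (two
#' per group) are amplified `marker_fold`-fold in their group; every
#' cell's protein rates are multiplied by a log-normal capture factor —
#' the technical component that background-based denoising must remove.
#' Empty droplets are drawn from the ambient component alone. Ground
#' truth (marker assignment, capture factors, ambient means) is stored in
#' `uns`.
#'
#' @param params a [sim_params()] object.
#' @param marker_fold amplification of a marker protein in its group.
#' @param capture_sigma log-normal sd of the per-cell capture factor.
#' @return A list with `container` (modalities `rna` and `prot`) and
#'   `empty` (droplets x proteins count matrix).
#' @export
simulate_citeseq <- function(params = sim_params(), marker_fold = 12,
                             capture_sigma = 0.25) {
  stopifnot(inherits(params, "SimParams"))
  withr::with_seed(params$seed, {
    n <- params$n_cells; P <- params$n_proteins; G <- params$n_groups
    lat <- sim_latent(n, G, params$k_factors)
    cells <- sprintf("cell%04d", seq_len(n))
    prots <- sprintf("prot%03d", seq_len(P))

    # RNA block (same construction as the multiome preset)
    W_rna <- matrix(stats::rnorm(params$n_genes * params$k_factors,
                                 sd = 1 / sqrt(params$k_factors)),
                    params$n_genes, params$k_factors)
    sf <- exp(stats::rnorm(n, 0, params$depth_lognormal_sigma))
    eta <- lat$Z %*% t(W_rna) +
      matrix(stats::rnorm(n * params$n_genes, 0, params$noise_sd), n, params$n_genes)
    eta <- sweep(eta, 2L, stats::rnorm(params$n_genes, 0.5, 0.5), "+")
    Xr <- matrix(stats::rpois(length(eta), softplus(eta) * sf), n, params$n_genes,
                 dimnames = list(cells, sprintf("gene%04d", seq_len(params$n_genes))))

    ambient <- exp(stats::rnorm(P, log(15), 0.5))
    nb_size <- 10
    markers <- integer(0)
    if (P >= 2L * G) {
      markers <- seq_len(2L * G)                     # proteins 1..2G are markers
      marker_group <- rep(seq_len(G), each = 2L)
    } else {
      markers <- seq_len(min(P, G))
      marker_group <- seq_along(markers)
    }
    capture <- exp(stats::rnorm(n, 0, capture_sigma))
    mu <- matrix(ambient, n, P, byrow = TRUE)
    for (i in seq_along(markers)) {
      g <- marker_group[i]
      in_g <- as.integer(lat$groups) == g
      mu[in_g, markers[i]] <- mu[in_g, markers[i]] * marker_fold
    }
    mu <- mu * capture
    Xp <- matrix(stats::rnbinom(length(mu), mu = mu, size = nb_size), n, P,
                 dimnames = list(cells, prots))
    empty <- matrix(stats::rnbinom(params$n_empty * P,
                                   mu = rep(ambient, each = params$n_empty),
                                   size = nb_size),
                    params$n_empty, P,
                    dimnames = list(sprintf("drop%05d", seq_len(params$n_empty)), prots))

    rna <- AnnotatedMatrix(Xr, obs = data.frame(group = lat$groups, row.names = cells))
    prot <- AnnotatedMatrix(Xp, obs = data.frame(group = lat$groups, row.names = cells))
    mc <- make_container(list(rna = rna, prot = prot))
    mc$uns$truth <- list(markers = markers, marker_group = marker_group,
                         ambient = ambient, capture = capture, nb_size = nb_size)
    mc$obs$group <- lat$groups
    list(container = mc, empty = empty)
  })
}

#' Randomly drop cells independently per modality
#'
#' Removes a seeded random fraction of cells from each modality
#' independently, then recomputes the global union axes — exercising
#' support for observations missing from some modalities.
#'
#' @param mc a `MuContainer`.
#' @param fraction fraction of cells to drop per modality (`0 <= f < 1`).
#' @param seed integer seed.
#' @return A `MuContainer` whose global axis is the union of the
#'   surviving per-modality cells.
#' @export
drop_cells_per_modality <- function(mc, fraction, seed = 1L) {
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  stop_if_stale(mc)
  if (fraction == 0) return(mc)
  withr::with_seed(as.integer(seed), {
    for (m in names(mc$mod)) {
      n <- nrow(mc$mod[[m]]$obs)
      n_drop <- floor(fraction * n)
      if (n_drop > 0) {
        keep <- sort(sample.int(n, n - n_drop))
        mc$mod[[m]] <- subset_annmatrix(mc$mod[[m]], i = keep)
      }
    }
    attr(mc, "stale") <- TRUE
    mu_update(mc)
  })
}
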