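#' Annotated matrix: one omics modality
#'
#' An `AnnotatedMatrix` bundles a primary observations x features matrix `X`
#' (dense, or sparse in compressed row/column form) with annotation tables for
#' both axes and named auxiliary slots, mirroring the single-omics container
#' layout used across the single-cell ecosystem:
#'
#' * `obs`, `var`: data frames indexed by unique observation / feature names;
#' * `layers`: named matrices with the same shape as `X`;
#' * `obsm`, `varm`: named matrices with one row per observation / feature
#'   (embeddings, loadings);
#' * `obsp`, `varp`: named square pairwise matrices (graphs, distances);
#' * `uns`: unstructured named metadata (scalars, vectors, nested lists).
#'
#' @param X numeric matrix or `Matrix` sparse matrix, observations in rows.
#' @param obs,var data frames with one row per observation / feature. Row
#'   names are the axis names; if `NULL`, names are taken from `dimnames(X)`.
#' @param layers,obsm,varm,obsp,varp,uns named lists; see above.
#'
#' @return An object of class `AnnotatedMatrix`.
#' @examples
#' am <- AnnotatedMatrix(matrix(rpois(12, 5), 3, 4,
#'   dimnames = list(paste0("c", 1:3), paste0("g", 1:4))))
#' dim(am)
#' @export
AnnotatedMatrix <- function(X, obs = NULL, var = NULL, layers = list(),
                            obsm = list(), varm = list(),
                            obsp = list(), varp = list(), uns = list()) {
  if (is.null(dim(X)) || length(dim(X)) != 2L)
    stop("X must be a two-dimensional matrix")
  if (is.null(obs)) {
    rn <- rownames(X)
    if (is.null(rn)) rn <- paste0("obs", seq_len(nrow(X)))
    if (anyDuplicated(rn))
      stop(sprintf("duplicate obs_names (e.g. '%s')", rn[duplicated(rn)][1L]))
    obs <- data.frame(row.names = rn)
  }
  if (is.null(var)) {
    cn <- colnames(X)
    if (is.null(cn)) cn <- paste0("var", seq_len(ncol(X)))
    if (anyDuplicated(cn))
      stop(sprintf("duplicate var_names (e.g. '%s')", cn[duplicated(cn)][1L]))
    var <- data.frame(row.names = cn)
  }
  obs <- as.data.frame(obs)
  var <- as.data.frame(var)
  am <- structure(
    list(X = X, obs = obs, var = var, layers = layers,
         obsm = obsm, varm = varm, obsp = obsp, varp = varp, uns = uns),
    class = "AnnotatedMatrix")
  validate_annmatrix(am)
  # axis names are owned by obs/var; keep X and layers labelled consistently
  if (!is_backed(am$X)) dimnames(am$X) <- list(rownames(obs), rownames(var))
  am$layers <- lapply(am$layers, function(m) {
    if (!is_backed(m)) dimnames(m) <- list(rownames(obs), rownames(var))
    m
  })
  am
}

#' @export
dim.AnnotatedMatrix <- function(x) c(nrow(x$obs), nrow(x$var))

#' Observation / feature names of a modality or container
#'
#' @param x an `AnnotatedMatrix` or `MuContainer`.
#' @return Character vector of names along the respective axis.
#' @export
obs_names <- function(x) UseMethod("obs_names")

#' @rdname obs_names
#' @export
var_names <- function(x) UseMethod("var_names")

#' @export
obs_names.AnnotatedMatrix <- function(x) rownames(x$obs)

#' @export
var_names.AnnotatedMatrix <- function(x) rownames(x$var)

#' Validate the internal consistency of an AnnotatedMatrix
#'
#' Checks unique axis names and the shape contracts of every slot entry.
#' Called by the constructor; exported because container-level operations
#' re-validate modalities after user mutation.
#'
#' @param am an `AnnotatedMatrix`.
#' @param name modality name used in error messages.
#' @return `am`, invisibly; errors describe the first violation found.
#' @export
validate_annmatrix <- function(am, name = "modality") {
  n <- nrow(am$obs); d <- nrow(am$var)
  on <- rownames(am$obs); vn <- rownames(am$var)
  if (anyDuplicated(on))
    stop(sprintf("%s: duplicate obs_names (e.g. '%s')", name, on[duplicated(on)][1L]))
  if (anyDuplicated(vn))
    stop(sprintf("%s: duplicate var_names (e.g. '%s')", name, vn[duplicated(vn)][1L]))
  if (!is_backed(am$X) && !identical(dim(am$X), c(n, d)) && !identical(dim(am$X), as.integer(c(n, d))))
    stop(sprintf("%s: X is %d x %d but obs/var imply %d x %d", name,
                 nrow(am$X), ncol(am$X), n, d))
  for (nm in names(am$layers)) {
    ly <- am$layers[[nm]]
    if (!is_backed(ly) && !all(dim(ly) == c(n, d)))
      stop(sprintf("%s: layer '%s' has shape %d x %d, expected %d x %d",
                   name, nm, nrow(ly), ncol(ly), n, d))
  }
  for (nm in names(am$obsm))
    if (nrow(am$obsm[[nm]]) != n)
      stop(sprintf("%s: obsm '%s' has %d rows, expected %d", name, nm, nrow(am$obsm[[nm]]), n))
  for (nm in names(am$varm))
    if (nrow(am$varm[[nm]]) != d)
      stop(sprintf("%s: varm '%s' has %d rows, expected %d", name, nm, nrow(am$varm[[nm]]), d))
  for (nm in names(am$obsp))
    if (!all(dim(am$obsp[[nm]]) == c(n, n)))
      stop(sprintf("%s: obsp '%s' must be %d x %d", name, nm, n, n))
  for (nm in names(am$varp))
    if (!all(dim(am$varp[[nm]]) == c(d, d)))
      stop(sprintf("%s: varp '%s' must be %d x %d", name, nm, d, d))
  invisible(am)
}

#' @export
print.AnnotatedMatrix <- function(x, ...) {
  cat(sprintf("AnnotatedMatrix  %d obs x %d var  (X: %s)\n",
              nrow(x$obs), nrow(x$var),
              if (is_backed(x$X)) "backed" else class(x$X)[1L]))
  for (slot in c("layers", "obsm", "varm", "obsp", "varp", "uns")) {
    nm <- names(x[[slot]])
    if (length(nm)) cat(sprintf("  %s: %s\n", slot, paste(nm, collapse = ", ")))
  }
  invisible(x)
}

# subset a modality by local integer indices (either may be NULL = keep all)
subset_annmatrix <- function(am, i = NULL, j = NULL) {
  if (is.null(i)) i <- seq_len(nrow(am$obs))
  if (is.null(j)) j <- seq_len(nrow(am$var))
  am$X <- am$X[i, j, drop = FALSE]
  am$obs <- am$obs[i, , drop = FALSE]
  am$var <- am$var[j, , drop = FALSE]
  am$layers <- lapply(am$layers, function(m) m[i, j, drop = FALSE])
  am$obsm <- lapply(am$obsm, function(m) m[i, , drop = FALSE])
  am$varm <- lapply(am$varm, function(m) m[j, , drop = FALSE])
  am$obsp <- lapply(am$obsp, function(m) m[i, i, drop = FALSE])
  am$varp <- lapply(am$varp, function(m) m[j, j, drop = FALSE])
  am
}
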