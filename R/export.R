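#' Export one modality to MatrixMarket or CSV files
#'
#' MTX export writes the 10x-style triplet: `matrix.mtx` (MatrixMarket
#' coordinate format, 1-based indices, features in rows x cells in
#' columns is *not* used — the matrix is written as observations x
#' features exactly as stored), `barcodes.tsv` (observation names) and
#' `features.tsv` (feature names). CSV export writes the dense matrix
#' with a header row and row names; it refuses matrices with more than
#' `max_cells` entries unless `force = TRUE`.
#'
#' @param mc a `MuContainer`.
#' @param name modality name.
#' @param dir output directory (created if needed).
#' @param format `"mtx"` or `"csv"`.
#' @param max_cells dense-export guard: maximum `n_obs * n_var`.
#' @param force override the dense-export guard.
#' @return Character vector of files written, invisibly.
#' @export
export_modality <- function(mc, name, dir, format = c("mtx", "csv"),
                            max_cells = 1e6, force = FALSE) {
  format <- match.arg(format)
  if (!name %in% names(mc$mod))
    stop(sprintf("unknown modality '%s' (available: %s)", name,
                 paste(names(mc$mod), collapse = ", ")))
  am <- mc$mod[[name]]
  X <- materialize(am$X)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "mtx") {
    sp <- methods::as(methods::as(methods::as(Matrix::Matrix(X, sparse = TRUE),
                                              "dMatrix"), "generalMatrix"), "TsparseMatrix")
    mtx <- file.path(dir, "matrix.mtx")
    Matrix::writeMM(sp, mtx)
    bc <- file.path(dir, "barcodes.tsv")
    ft <- file.path(dir, "features.tsv")
    writeLines(obs_names(am), bc)
    writeLines(var_names(am), ft)
    invisible(c(mtx, bc, ft))
  } else {
    if (prod(dim(X)) > max_cells && !force)
      stop(sprintf("dense export of %d x %d matrix exceeds max_cells = %g; pass force = TRUE",
                   nrow(X), ncol(X), max_cells))
    f <- file.path(dir, paste0(name, ".csv"))
    dn <- as.matrix(X)
    dimnames(dn) <- list(obs_names(am), var_names(am))
    utils::write.csv(dn, f)
    invisible(f)
  }
}

#' Import a MatrixMarket triplet directory as an AnnotatedMatrix
#'
#' Inverse of the MTX branch of [export_modality()].
#'
#' @param dir directory containing `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv`.
#' @return An [AnnotatedMatrix()] with a row-sparse `X`.
#' @export
import_mtx <- function(dir) {
  X <- methods::as(methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix"),
                   "RsparseMatrix")
  X <- methods::as(methods::as(X, "dMatrix"), "generalMatrix")
  bc <- readLines(file.path(dir, "barcodes.tsv"))
  ft <- readLines(file.path(dir, "features.tsv"))
  AnnotatedMatrix(X, obs = data.frame(row.names = bc), var = data.frame(row.names = ft))
}
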