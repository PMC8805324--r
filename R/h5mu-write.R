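H5MU_VERSION <- "0.1.0"

#' Serialise a container to a .h5mu file
#'
#' Writes the self-describing HDF5 dialect: root attributes
#' `encoding-type = "MuData"`, `encoding-version`, `generator`; a `mod`
#' group (attribute `mod-order`) holding one standalone modality subtree
#' per modality (attribute `encoding-type = "AnnData"`); top-level `obs`,
#' `var`, `obsm`, `varm`, `obsp`, `varp`, `uns` plus the per-modality axis
#' maps under `obsmap`/`varmap`.
#'
#' Encodings: dense matrices are 2-D datasets in observation-major
#' (C-order) shape; sparse matrices are groups with
#' `encoding-type = "csr_matrix"`, a `shape` attribute and `data`,
#' `indices` (0-based, row-sorted), `indptr` datasets (column-compressed
#' inputs are converted to row-compressed form on write); annotation
#' tables are groups with `encoding-type = "dataframe"`, `_index` and
#' `column-order` attributes, categorical columns as `{codes, categories}`
#' subgroups (code -1 = missing); logicals as int8 with
#' `encoding-type = "boolean"` (-1 = missing); strings UTF-8
#' variable-length. Integer columns containing missing values are stored
#' as floats with `encoding-type = "integer"` so the dtype is restored on
#' read.
#'
#' The write is atomic: content goes to a temporary sibling file which is
#' renamed over `path` on success. Datasets larger than
#' `compress_threshold` bytes are gzip-compressed at `compression`.
#'
#' @param mc a `MuContainer` (not stale).
#' @param path output file path (conventionally `.h5mu`).
#' @param compression gzip level for large datasets (0 disables).
#' @param compress_threshold only datasets above this raw size (bytes) are
#'   compressed; small files stay `h5dump`-inspectable.
#' @return `path`, invisibly.
#' @export
write_h5mu <- function(mc, path, compression = 4L, compress_threshold = 65536) {
  stopifnot(inherits(mc, "MuContainer"))
  stop_if_stale(mc)
  tmp <- paste0(path, ".tmp-", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  rhdf5::h5createFile(tmp)
  fid <- rhdf5::H5Fopen(tmp)
  ok <- FALSE
  on.exit(try(rhdf5::H5Fclose(fid), silent = TRUE), add = TRUE, after = FALSE)
  wr <- function(name, value) h5_write_dataset(fid, name, value,
                                               threshold = compress_threshold,
                                               level = compression)

  h5_write_attr(fid, "/", "encoding-type", "MuData", scalar = TRUE)
  h5_write_attr(fid, "/", "encoding-version", H5MU_VERSION, scalar = TRUE)
  gen <- tryCatch(paste0("mudkit-", utils::packageVersion("mudkit")),
                  error = function(e) "mudkit")
  h5_write_attr(fid, "/", "generator", gen, scalar = TRUE)

  rhdf5::h5createGroup(fid, "mod")
  h5_write_attr(fid, "mod", "mod-order", names(mc$mod))
  for (m in names(mc$mod))
    write_annmatrix_group(fid, paste0("mod/", m), mc$mod[[m]], wr, uns_path = m)

  write_dataframe_group(fid, "obs", mc$obs, wr)
  write_dataframe_group(fid, "var", mc$var, wr)
  write_mapping_group(fid, "obsm", mc$obsm, wr)
  write_mapping_group(fid, "varm", mc$varm, wr)
  write_mapping_group(fid, "obsp", mc$obsp, wr)
  write_mapping_group(fid, "varp", mc$varp, wr)
  write_uns_group(fid, "uns", mc$uns, wr, key_path = "uns")
  rhdf5::h5createGroup(fid, "obsmap")
  for (m in names(mc$obsmap)) wr(paste0("obsmap/", m), as.integer(mc$obsmap[[m]]))
  rhdf5::h5createGroup(fid, "varmap")
  for (m in names(mc$varmap)) wr(paste0("varmap/", m), as.integer(mc$varmap[[m]]))

  rhdf5::H5Fclose(fid)
  ok <- TRUE
  if (!file.rename(tmp, path)) {
    # cross-device fallback
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

write_annmatrix_group <- function(fid, base, am, wr, uns_path = base) {
  rhdf5::h5createGroup(fid, base)
  h5_write_attr(fid, base, "encoding-type", "AnnData", scalar = TRUE)
  h5_write_attr(fid, base, "encoding-version", H5MU_VERSION, scalar = TRUE)
  write_matrix_elem(fid, paste0(base, "/X"), am$X, wr)
  rhdf5::h5createGroup(fid, paste0(base, "/layers"))
  for (nm in names(am$layers))
    write_matrix_elem(fid, paste0(base, "/layers/", nm), am$layers[[nm]], wr)
  write_dataframe_group(fid, paste0(base, "/obs"), am$obs, wr)
  write_dataframe_group(fid, paste0(base, "/var"), am$var, wr)
  write_mapping_group(fid, paste0(base, "/obsm"), am$obsm, wr)
  write_mapping_group(fid, paste0(base, "/varm"), am$varm, wr)
  write_mapping_group(fid, paste0(base, "/obsp"), am$obsp, wr)
  write_mapping_group(fid, paste0(base, "/varp"), am$varp, wr)
  write_uns_group(fid, paste0(base, "/uns"), am$uns, wr,
                  key_path = paste0(uns_path, "/uns"))
}

write_matrix_elem <- function(fid, name, m, wr) {
  if (is_backed(m)) m <- materialize(m)
  if (inherits(m, "sparseMatrix")) {
    m <- methods::as(m, "generalMatrix")
    m <- methods::as(m, "RsparseMatrix")     # canonical on-disk layout is CSR
    rhdf5::h5createGroup(fid, name)
    h5_write_attr(fid, name, "encoding-type", "csr_matrix", scalar = TRUE)
    h5_write_attr(fid, name, "encoding-version", H5MU_VERSION, scalar = TRUE)
    h5_write_attr(fid, name, "shape", as.integer(dim(m)))
    wr(paste0(name, "/data"), as.double(m@x))
    wr(paste0(name, "/indices"), as.integer(m@j))
    wr(paste0(name, "/indptr"), as.integer(m@p))
  } else {
    m <- as.matrix(m)
    dimnames(m) <- NULL
    wr(name, m)
    h5_write_attr(fid, name, "encoding-type", "array", scalar = TRUE)
  }
}

write_dataframe_group <- function(fid, name, df, wr) {
  rhdf5::h5createGroup(fid, name)
  h5_write_attr(fid, name, "encoding-type", "dataframe", scalar = TRUE)
  h5_write_attr(fid, name, "encoding-version", H5MU_VERSION, scalar = TRUE)
  h5_write_attr(fid, name, "_index", "_index", scalar = TRUE)
  h5_write_attr(fid, name, "column-order",
                if (ncol(df)) colnames(df) else "")
  wr(paste0(name, "/_index"), as.character(rownames(df)))
  for (cl in colnames(df))
    write_column(fid, paste0(name, "/", cl), df[[cl]], wr,
                 key_path = paste0(name, "/", cl))
}

write_column <- function(fid, name, v, wr, key_path = name) {
  if (is.factor(v)) {
    rhdf5::h5createGroup(fid, name)
    h5_write_attr(fid, name, "encoding-type", "categorical", scalar = TRUE)
    h5_write_attr(fid, name, "ordered", as.integer(is.ordered(v)), scalar = TRUE)
    codes <- as.integer(v) - 1L
    codes[is.na(codes)] <- -1L
    wr(paste0(name, "/codes"), codes)
    wr(paste0(name, "/categories"), levels(v))
  } else if (is.logical(v)) {
    iv <- as.integer(v)
    iv[is.na(iv)] <- -1L
    wr(name, as_int8(iv))
    h5_write_attr(fid, name, "encoding-type", "boolean", scalar = TRUE)
  } else if (is.integer(v)) {
    if (anyNA(v)) {
      dv <- as.double(v)                     # NA_real_ marks the gaps
      wr(name, dv)
      h5_write_attr(fid, name, "encoding-type", "integer", scalar = TRUE)
    } else {
      wr(name, v)
    }
  } else if (is.numeric(v)) {
    wr(name, as.double(v))
  } else if (is.character(v)) {
    if (anyNA(v))
      stop(sprintf("string column '%s' contains missing values; use a factor column instead",
                   key_path))
    wr(name, v)
    h5_write_attr(fid, name, "encoding-type", "string-array", scalar = TRUE)
  } else {
    stop(sprintf("cannot serialise column '%s' of class %s", key_path, class(v)[1L]))
  }
}

write_mapping_group <- function(fid, name, slots, wr) {
  rhdf5::h5createGroup(fid, name)
  for (nm in names(slots))
    write_matrix_elem(fid, paste0(name, "/", nm), slots[[nm]], wr)
}

write_uns_group <- function(fid, name, uns, wr, key_path = name) {
  rhdf5::h5createGroup(fid, name)
  for (nm in names(uns))
    write_uns_elem(fid, paste0(name, "/", nm), uns[[nm]], wr,
                   key_path = paste0(key_path, "/", nm))
}

write_uns_elem <- function(fid, name, v, wr, key_path) {
  if (is.list(v)) {
    if (length(v) && (is.null(names(v)) || any(!nzchar(names(v)))))
      stop(sprintf("uns entry '%s': only named lists can be serialised", key_path))
    write_uns_group(fid, name, v, wr, key_path = key_path)
  } else if (is.factor(v)) {
    write_column(fid, name, v, wr, key_path = key_path)
  } else if (is.matrix(v) && is.numeric(v)) {
    m <- v; dimnames(m) <- NULL
    wr(name, m)
  } else if (is.atomic(v) && (is.numeric(v) || is.character(v) || is.logical(v))) {
    write_column(fid, name, v, wr, key_path = key_path)
  } else {
    stop(sprintf("uns entry '%s' of class %s cannot be serialised (scalars, arrays, strings and named lists only)",
                 key_path, class(v)[1L]))
  }
}
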