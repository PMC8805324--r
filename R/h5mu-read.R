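#' Read a .h5mu file
#'
#' Reconstructs a `MuContainer` from the on-disk dialect written by
#' [write_h5mu()]. With `backed = TRUE` all annotation tables, axis maps,
#' embeddings and unstructured metadata are loaded, but each modality's
#' `X` and `layers` are replaced by lazy handles (class `H5BackedMatrix`)
#' that know their shape and only read matrix content when sliced or
#' materialised — so a file can be inspected without loading counts.
#'
#' @param path path to a conforming `.h5mu` file.
#' @param backed keep count matrices on disk?
#' @return A `MuContainer`.
#' @seealso [read_modality()], [validate_h5mu()], [materialize()]
#' @export
read_h5mu <- function(path, backed = FALSE) {
  check_h5mu_header(path)
  ls <- rhdf5::h5ls(path)
  mods <- h5mu_mod_order(path)
  mod <- stats::setNames(
    lapply(mods, function(m) read_annmatrix_group(path, paste0("/mod/", m), ls, backed)),
    mods)
  mc <- structure(
    list(mod = mod,
         obs = read_dataframe_group(path, "/obs", ls),
         var = read_dataframe_group(path, "/var", ls),
         obsm = read_mapping_group(path, "/obsm", ls),
         varm = read_mapping_group(path, "/varm", ls),
         obsp = read_mapping_group(path, "/obsp", ls),
         varp = read_mapping_group(path, "/varp", ls),
         uns = read_uns_group(path, "/uns", ls),
         obsmap = stats::setNames(lapply(mods, function(m)
           as.integer(h5read_tracked(path, paste0("/obsmap/", m)))), mods),
         varmap = stats::setNames(lapply(mods, function(m)
           as.integer(h5read_tracked(path, paste0("/varmap/", m)))), mods),
         pulled = list(obs = character(), var = character())),
    class = "MuContainer", stale = FALSE)
  # reconstruct which global columns are auto-pulled modality columns
  for (m in mods) {
    po <- paste0(m, ":", colnames(mc$mod[[m]]$obs))
    pv <- paste0(m, ":", colnames(mc$mod[[m]]$var))
    mc$pulled$obs <- c(mc$pulled$obs, intersect(po, colnames(mc$obs)))
    mc$pulled$var <- c(mc$pulled$var, intersect(pv, colnames(mc$var)))
  }
  mc
}

#' Read a single modality from a .h5mu file
#'
#' Reads exactly one modality subtree; datasets belonging to other
#' modalities are not touched (verifiable via [h5_read_stats()]).
#'
#' @param path path to a `.h5mu` file.
#' @param name modality name (must appear in the file's `mod-order`).
#' @param backed keep `X`/layers on disk?
#' @return An [AnnotatedMatrix()].
#' @export
read_modality <- function(path, name, backed = FALSE) {
  check_h5mu_header(path)
  mods <- h5mu_mod_order(path)
  if (!name %in% mods)
    stop(sprintf("unknown modality '%s'; file contains: %s",
                 name, paste(mods, collapse = ", ")))
  ls <- rhdf5::h5ls(path)
  read_annmatrix_group(path, paste0("/mod/", name), ls, backed)
}

#' Read a standalone modality (AnnData-layout) subtree
#'
#' The per-modality subtrees of a `.h5mu` file are self-contained: copied
#' to the root of a fresh HDF5 file they remain readable. This reader
#' decodes such a subtree at an arbitrary base path; [read_modality()]
#' delegates to it.
#'
#' @param path HDF5 file.
#' @param base in-file path of the subtree (default the file root).
#' @param backed keep `X`/layers on disk?
#' @return An [AnnotatedMatrix()].
#' @export
read_anndata_h5 <- function(path, base = "/", backed = FALSE) {
  base <- sub("/$", "", base)
  ls <- rhdf5::h5ls(path)
  read_annmatrix_group(path, if (nzchar(base)) base else "", ls, backed)
}

check_h5mu_header <- function(path) {
  if (!file.exists(path))
    stop(errorCondition(sprintf("file not found: %s", path),
                        class = c("mudkit_io_error", "error")))
  if (!isTRUE(rhdf5::H5Fis_hdf5(path)))
    stop(errorCondition(sprintf("not an HDF5 file: %s", path),
                        class = c("mudkit_not_hdf5", "error")))
  at <- h5_attrs(path, "/")
  if (!identical(as.vector(at[["encoding-type"]]), "MuData"))
    stop(errorCondition(sprintf("%s: missing or wrong root encoding-type (expected 'MuData')", path),
                        class = c("mudkit_format_error", "error")))
  ver <- as.vector(at[["encoding-version"]])
  if (is.null(ver))
    stop(errorCondition(sprintf("%s: missing encoding-version", path),
                        class = c("mudkit_format_error", "error")))
  if (strsplit(ver, ".", fixed = TRUE)[[1]][1] != strsplit(H5MU_VERSION, ".", fixed = TRUE)[[1]][1])
    stop(errorCondition(
      sprintf("%s: unsupported encoding-version '%s' (reader supports major version %s)",
              path, ver, strsplit(H5MU_VERSION, ".", fixed = TRUE)[[1]][1]),
      class = c("mudkit_version_error", "mudkit_format_error", "error")))
  ls0 <- rhdf5::h5ls(path, recursive = FALSE)
  if (!"mod" %in% ls0$name)
    stop(errorCondition(sprintf("%s: no 'mod' group", path),
                        class = c("mudkit_format_error", "error")))
  invisible(path)
}

h5mu_mod_order <- function(path) as.vector(h5_attr1(path, "mod", "mod-order"))

ls_children <- function(ls, base) {
  ls$name[ls$group == base]
}

ls_entry <- function(ls, path) {
  dir <- dirname(path); if (dir == ".") dir <- "/"
  ls[ls$group == dir & ls$name == basename(path), , drop = FALSE]
}

read_annmatrix_group <- function(path, base, ls, backed = FALSE) {
  obs <- read_dataframe_group(path, paste0(base, "/obs"), ls)
  var <- read_dataframe_group(path, paste0(base, "/var"), ls)
  X <- read_matrix_elem(path, paste0(base, "/X"), ls, backed)
  layer_names <- ls_children(ls, paste0(base, "/layers"))
  layers <- stats::setNames(lapply(layer_names, function(nm)
    read_matrix_elem(path, paste0(base, "/layers/", nm), ls, backed)), layer_names)
  AnnotatedMatrix(
    X = X, obs = obs, var = var, layers = layers,
    obsm = read_mapping_group(path, paste0(base, "/obsm"), ls),
    varm = read_mapping_group(path, paste0(base, "/varm"), ls),
    obsp = read_mapping_group(path, paste0(base, "/obsp"), ls),
    varp = read_mapping_group(path, paste0(base, "/varp"), ls),
    uns = read_uns_group(path, paste0(base, "/uns"), ls))
}

read_matrix_elem <- function(path, name, ls, backed = FALSE) {
  entry <- ls_entry(ls, name)
  if (nrow(entry) == 0L)
    stop(errorCondition(sprintf("%s: missing element '%s'", path, name),
                        class = c("mudkit_format_error", "error")))
  if (entry$otype == "H5I_GROUP") {
    at <- h5_attrs(path, name)
    enc <- as.vector(at[["encoding-type"]])
    if (!identical(enc, "csr_matrix"))
      stop(errorCondition(sprintf("%s: unknown matrix encoding '%s' at %s", path, enc, name),
                          class = c("mudkit_format_error", "error")))
    shape <- as.integer(at[["shape"]])
    if (backed)
      return(new_backed(path, name, shape, kind = "csr"))
    methods::new("dgRMatrix",
                 p = as.integer(h5read_tracked(path, paste0(name, "/indptr"))),
                 j = as.integer(h5read_tracked(path, paste0(name, "/indices"))),
                 x = as.double(h5read_tracked(path, paste0(name, "/data"))),
                 Dim = shape)
  } else {
    if (backed) {
      d <- as.integer(strsplit(entry$dim, " x ")[[1]])  # R-side dims (transposed)
      return(new_backed(path, name, rev(d), kind = "dense"))
    }
    t(h5read_tracked(path, name))
  }
}

read_dataframe_group <- function(path, name, ls) {
  at <- h5_attrs(path, name)
  idx_name <- as.vector(at[["_index"]]); if (is.null(idx_name)) idx_name <- "_index"
  index <- as.character(h5read_tracked(path, paste0(name, "/", idx_name)))
  cols <- as.vector(at[["column-order"]])
  cols <- cols[nzchar(cols)]
  df <- data.frame(row.names = index)
  for (cl in cols) df[[cl]] <- read_column(path, paste0(name, "/", cl), ls)
  df
}

read_column <- function(path, name, ls) {
  entry <- ls_entry(ls, name)
  if (nrow(entry) == 0L)
    stop(errorCondition(sprintf("%s: missing column dataset '%s'", path, name),
                        class = c("mudkit_format_error", "error")))
  if (entry$otype == "H5I_GROUP") {            # categorical
    at <- h5_attrs(path, name)
    codes <- as.integer(h5read_tracked(path, paste0(name, "/codes")))
    cats <- as.character(h5read_tracked(path, paste0(name, "/categories")))
    codes[codes < 0L] <- NA_integer_
    factor(cats[codes + 1L], levels = cats,
           ordered = isTRUE(as.vector(at[["ordered"]]) == 1L))
  } else {
    v <- h5read_tracked(path, name)
    enc <- h5_attr1(path, name, "encoding-type")
    if (identical(enc, "boolean")) {
      v <- as.integer(v)
      out <- v == 1L
      out[v < 0L] <- NA
      out
    } else if (identical(enc, "integer")) {
      out <- suppressWarnings(as.integer(v))
      out[is.na(v)] <- NA_integer_
      out
    } else if (is.character(v)) {
      as.character(v)
    } else {
      as.vector(v)
    }
  }
}

read_mapping_group <- function(path, name, ls) {
  nms <- ls_children(ls, name)
  stats::setNames(lapply(nms, function(nm)
    read_matrix_elem(path, paste0(name, "/", nm), ls, backed = FALSE)), nms)
}

read_uns_group <- function(path, name, ls) {
  nms <- ls_children(ls, name)
  stats::setNames(lapply(nms, function(nm)
    read_uns_elem(path, paste0(name, "/", nm), ls)), nms)
}

read_uns_elem <- function(path, name, ls) {
  entry <- ls_entry(ls, name)
  if (entry$otype == "H5I_GROUP") {
    enc <- h5_attr1(path, name, "encoding-type")
    if (identical(enc, "categorical")) return(read_column(path, name, ls))
    if (identical(enc, "csr_matrix")) return(read_matrix_elem(path, name, ls))
    return(read_uns_group(path, name, ls))
  }
  v <- h5read_tracked(path, name)
  enc <- h5_attr1(path, name, "encoding-type")
  if (identical(enc, "boolean")) {
    v <- as.integer(v); out <- v == 1L; out[v < 0L] <- NA
    return(out)
  }
  if (identical(enc, "integer")) {
    out <- suppressWarnings(as.integer(v)); out[is.na(v)] <- NA_integer_
    return(out)
  }
  if (is.matrix(v)) return(t(v))
  if (is.character(v)) return(as.character(v))
  as.vector(v)
}
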