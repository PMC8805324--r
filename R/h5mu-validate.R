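#' Validate a .h5mu file against the layout contract
#'
#' Checks the structural rules of the dialect: root attributes, the `mod`
#' group and `mod-order`, per-modality encoding attributes, annotation
#' table encodings, matrix shape consistency against the axis lengths,
#' sparse-group completeness, axis-map lengths and the axis-map value
#' contract (nonzero entries a permutation of the local axis, in
#' increasing order). The default pass reads only metadata and small map
#' datasets — never `X`/layer content — so it is safe on backed workflows;
#' `deep = TRUE` additionally reads sparse index arrays to check index
#' range and per-row sortedness.
#'
#' @param path path to a candidate file.
#' @param deep also verify sparse index content?
#' @return Character vector of violations; empty iff the file conforms.
#'   A non-HDF5 input raises an error of class `mudkit_not_hdf5`.
#' @export
validate_h5mu <- function(path, deep = FALSE) {
  if (!file.exists(path))
    stop(errorCondition(sprintf("file not found: %s", path),
                        class = c("mudkit_io_error", "error")))
  if (!isTRUE(rhdf5::H5Fis_hdf5(path)))
    stop(errorCondition(sprintf("not an HDF5 file: %s", path),
                        class = c("mudkit_not_hdf5", "error")))
  v <- character()
  bad <- function(fmt, ...) v <<- c(v, sprintf(fmt, ...))

  at <- h5_attrs(path, "/")
  if (!identical(as.vector(at[["encoding-type"]]), "MuData"))
    bad("root: encoding-type is not 'MuData'")
  ver <- as.vector(at[["encoding-version"]])
  if (is.null(ver)) bad("root: missing encoding-version")
  else if (strsplit(ver, ".", fixed = TRUE)[[1]][1] !=
           strsplit(H5MU_VERSION, ".", fixed = TRUE)[[1]][1])
    bad("root: unsupported encoding-version '%s'", ver)

  ls <- rhdf5::h5ls(path)
  ls0 <- ls$name[ls$group == "/"]
  for (req in c("mod", "obs", "var", "obsmap", "varmap"))
    if (!req %in% ls0) bad("root: missing '%s' group", req)
  if (length(v)) return(v)

  mods <- as.vector(h5_attr1(path, "mod", "mod-order"))
  groups_present <- ls$name[ls$group == "/mod"]
  if (is.null(mods)) {
    bad("mod: missing mod-order attribute")
    mods <- groups_present
  } else {
    for (m in setdiff(mods, groups_present)) bad("mod: '%s' in mod-order but absent", m)
    for (m in setdiff(groups_present, mods)) bad("mod: group '%s' not in mod-order", m)
    mods <- intersect(mods, groups_present)
  }

  n_obs_global <- df_index_length(path, "/obs", ls, bad, "obs")
  n_var_global <- df_index_length(path, "/var", ls, bad, "var")

  for (m in mods) {
    base <- paste0("/mod/", m)
    enc <- h5_attr1(path, base, "encoding-type")
    if (!identical(as.vector(enc), "AnnData"))
      bad("%s: encoding-type is not 'AnnData'", base)
    n <- df_index_length(path, paste0(base, "/obs"), ls, bad, paste0(base, "/obs"))
    d <- df_index_length(path, paste0(base, "/var"), ls, bad, paste0(base, "/var"))
    check_matrix_shape(path, paste0(base, "/X"), ls, n, d, bad, deep)
    for (ly in ls_children(ls, paste0(base, "/layers")))
      check_matrix_shape(path, paste0(base, "/layers/", ly), ls, n, d, bad, deep)
    for (e in ls_children(ls, paste0(base, "/obsm")))
      check_matrix_shape(path, paste0(base, "/obsm/", e), ls, n, NA, bad, deep)
    for (e in ls_children(ls, paste0(base, "/obsp")))
      check_matrix_shape(path, paste0(base, "/obsp/", e), ls, n, n, bad, deep)

    # axis maps
    for (ax in c("obsmap", "varmap")) {
      mp_path <- paste0("/", ax, "/", m)
      if (nrow(ls_entry(ls, mp_path)) == 0L) {
        bad("%s: missing axis map for modality '%s'", ax, m)
        next
      }
      mp <- as.integer(h5read_tracked(path, mp_path))
      n_glob <- if (ax == "obsmap") n_obs_global else n_var_global
      n_loc <- if (ax == "obsmap") n else d
      if (!is.na(n_glob) && length(mp) != n_glob)
        bad("%s/%s: axis-map length mismatch (%d, global axis has %d)",
            ax, m, length(mp), n_glob)
      nz <- mp[mp > 0L]
      if (!is.na(n_loc) && !identical(sort(nz), seq_len(n_loc)[seq_along(nz)]) ||
          (!is.na(n_loc) && length(nz) != n_loc))
        bad("%s/%s: nonzero entries are not a permutation of 1..%d", ax, m, n_loc)
      if (is.unsorted(nz, strictly = TRUE))
        bad("%s/%s: nonzero entries not increasing (order-preserving contract)", ax, m)
    }
  }

  for (e in ls_children(ls, "/obsm"))
    check_matrix_shape(path, paste0("/obsm/", e), ls, n_obs_global, NA, bad, deep)
  for (e in ls_children(ls, "/obsp"))
    check_matrix_shape(path, paste0("/obsp/", e), ls, n_obs_global, n_obs_global, bad, deep)
  for (e in ls_children(ls, "/varp"))
    check_matrix_shape(path, paste0("/varp/", e), ls, n_var_global, n_var_global, bad, deep)
  v
}

# index length of a dataframe group, reporting encoding violations
df_index_length <- function(path, name, ls, bad, label) {
  if (nrow(ls_entry(ls, name)) == 0L) {
    bad("%s: missing annotation group", label)
    return(NA_integer_)
  }
  at <- h5_attrs(path, name)
  if (!identical(as.vector(at[["encoding-type"]]), "dataframe"))
    bad("%s: encoding-type is not 'dataframe'", label)
  idx <- as.vector(at[["_index"]]); if (is.null(idx)) {
    bad("%s: missing _index attribute", label)
    idx <- "_index"
  }
  entry <- ls_entry(ls, paste0(name, "/", idx))
  if (nrow(entry) == 0L) {
    bad("%s: missing index dataset '%s'", label, idx)
    return(NA_integer_)
  }
  as.integer(entry$dim)
}

check_matrix_shape <- function(path, name, ls, n, d, bad, deep) {
  entry <- ls_entry(ls, name)
  if (nrow(entry) == 0L) {
    bad("%s: missing matrix element", name)
    return(invisible())
  }
  if (entry$otype == "H5I_GROUP") {
    at <- h5_attrs(path, name)
    if (!identical(as.vector(at[["encoding-type"]]), "csr_matrix"))
      bad("%s: sparse group without encoding-type 'csr_matrix'", name)
    shape <- as.integer(at[["shape"]])
    if (length(shape) != 2L) {
      bad("%s: missing/invalid shape attribute", name)
      return(invisible())
    }
    if (!is.na(n) && shape[1] != n) bad("%s: shape[1] = %d, expected %d", name, shape[1], n)
    if (!is.na(d) && shape[2] != d) bad("%s: shape[2] = %d, expected %d", name, shape[2], d)
    kids <- ls_children(ls, name)
    for (req in c("data", "indices", "indptr"))
      if (!req %in% kids) bad("%s: CSR group missing '%s'", name, req)
    if ("indptr" %in% kids) {
      len <- as.integer(ls_entry(ls, paste0(name, "/indptr"))$dim)
      if (len != shape[1] + 1L)
        bad("%s: indptr length %d, expected %d", name, len, shape[1] + 1L)
    }
    if (deep && all(c("data", "indices", "indptr") %in% kids)) {
      idx <- as.integer(h5read_tracked(path, paste0(name, "/indices")))
      ptr <- as.integer(h5read_tracked(path, paste0(name, "/indptr")))
      if (length(idx) && (min(idx) < 0L || max(idx) >= shape[2]))
        bad("%s: indices out of [0, %d)", name, shape[2])
      for (r in seq_len(shape[1])) {
        seg <- idx[(ptr[r] + 1L):ptr[r + 1L]]
        if (ptr[r + 1L] > ptr[r] && is.unsorted(seg, strictly = TRUE)) {
          bad("%s: indices of row %d not strictly sorted", name, r)
          break
        }
      }
    }
  } else {
    dims <- rev(as.integer(strsplit(entry$dim, " x ")[[1]]))
    if (length(dims) != 2L) {
      bad("%s: dense matrix element is not 2-D", name)
      return(invisible())
    }
    if (!is.na(n) && dims[1] != n) bad("%s: %d rows, expected %d", name, dims[1], n)
    if (!is.na(d) && dims[2] != d) bad("%s: %d columns, expected %d", name, dims[2], d)
  }
  invisible()
}
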