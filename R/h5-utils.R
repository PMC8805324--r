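# Low-level HDF5 helpers shared by the .h5mu writer, reader and validator.
# All dataset reads funnel through h5read_tracked() so tests (and the
# backed-mode contract) can assert which datasets were touched.

.mud_env <- new.env(parent = emptyenv())
.mud_env$reads <- character()

#' Instrumented dataset-read log
#'
#' Every HDF5 dataset read performed by the package's readers is recorded
#' (by in-file path). `h5_reset_read_stats()` clears the log;
#' `h5_read_stats()` returns the paths read since the last reset. Used to
#' verify the disk-backed contract: metadata access must not touch count
#' matrices.
#'
#' @return `h5_read_stats()`: character vector of dataset paths.
#' @export
h5_read_stats <- function() .mud_env$reads

#' @rdname h5_read_stats
#' @export
h5_reset_read_stats <- function() {
  .mud_env$reads <- character()
  invisible(NULL)
}

h5read_tracked <- function(file, name, index = NULL) {
  .mud_env$reads <- c(.mud_env$reads, name)
  if (is.null(index)) rhdf5::h5read(file, name)
  else rhdf5::h5read(file, name, index = index)
}

h5_attrs <- function(file, path) rhdf5::h5readAttributes(file, path)

h5_attr1 <- function(file, path, name) {
  a <- h5_attrs(file, path)[[name]]
  if (is.null(a)) NULL else as.vector(a)
}

# ---- writer-side helpers (operate on an open H5IdComponent) --------------

h5_write_attr <- function(fid, objpath, name, value, scalar = FALSE) {
  obj <- rhdf5::H5Oopen(fid, objpath)
  on.exit(rhdf5::H5Oclose(obj))
  if (is.character(value)) {
    rhdf5::h5writeAttribute(value, obj, name, variableLengthString = TRUE,
                            asScalar = scalar, encoding = "UTF-8")
  } else {
    rhdf5::h5writeAttribute(value, obj, name, asScalar = scalar)
  }
}

# gzip datasets whose raw size exceeds the threshold (bytes)
.compress_level <- function(value, threshold, level) {
  nbytes <- length(value) * 8L
  if (is.character(value)) nbytes <- sum(nchar(value, type = "bytes"))
  if (nbytes > threshold) level else 0L
}

# write a vector or matrix dataset; matrices are written transposed so the
# on-disk (C-order) shape is the R shape, matching the h5py convention.
h5_write_dataset <- function(fid, name, value, threshold = 65536, level = 4L) {
  if (is.matrix(value)) value <- t(value)
  dims <- if (is.matrix(value)) dim(value) else length(value)
  lvl <- .compress_level(value, threshold, level)
  if (is.character(value)) {
    rhdf5::h5createDataset(fid, name, dims = dims, storage.mode = "character",
                           size = NULL, encoding = "UTF-8", level = lvl,
                           shuffle = FALSE)
  } else if (inherits(value, "int8")) {
    rhdf5::h5createDataset(fid, name, dims = dims, storage.mode = "integer",
                           H5type = "H5T_NATIVE_INT8", level = lvl, shuffle = FALSE)
    value <- unclass(value)
  } else {
    storage <- if (is.integer(value)) "integer" else "double"
    rhdf5::h5createDataset(fid, name, dims = dims, storage.mode = storage,
                           level = lvl, shuffle = FALSE)
  }
  if (length(value) > 0) rhdf5::h5write(value, fid, name)
  invisible(name)
}

as_int8 <- function(x) structure(as.integer(x), class = "int8")
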